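#' Validate and normalise a genotype table
#'
#' Genotype tables are long tibbles with one row per sample x locus: columns
#' `sample_id`, `locus`, and allele fragment sizes `a1`..`a4` in bp (integer,
#' `NA` for unrecorded). A row with all four sizes missing is a missing
#' genotype. Sample and locus order follow first appearance.
#'
#' @param x A data frame in the layout above.
#' @return A validated tibble with integer allele columns.
#' @export
as_genotype_table <- function(x) {
  need <- c("sample_id", "locus", "a1", "a2", "a3", "a4")
  if (!all(need %in% names(x))) {
    stop("genotype table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)[need]
  for (a in c("a1", "a2", "a3", "a4")) {
    v <- x[[a]]
    if (is.character(v)) {
      v <- dplyr::na_if(trimws(v), "")
      unparsed <- !is.na(v) & is.na(suppressWarnings(as.numeric(v)))
      if (any(unparsed)) {
        stop(sprintf("non-numeric allele size '%s' in column %s, row %d",
                     v[which(unparsed)[1]], a, which(unparsed)[1]),
             call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(v))
    }
    if (any(!is.na(v) & (v <= 0 | v != round(v)))) {
      bad <- which(!is.na(v) & (v <= 0 | v != round(v)))[1]
      stop(sprintf("allele size in column %s, row %d is not a positive integer",
                   a, bad), call. = FALSE)
    }
    x[[a]] <- as.integer(v)
  }
  gap <- (is.na(x$a1) & !is.na(x$a2)) | (is.na(x$a2) & !is.na(x$a3)) |
    (is.na(x$a3) & !is.na(x$a4))
  if (any(gap)) {
    stop("rows with a later allele recorded before an earlier one: ",
         paste(utils::head(which(gap), 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x[c("sample_id", "locus")])) {
    stop("duplicated sample_id/locus rows", call. = FALSE)
  }
  x
}

sample_order <- function(tbl) unique(tbl$sample_id)
locus_order <- function(tbl) unique(tbl$locus)

#' Diploid view of a genotype table
#'
#' Statistics are computed on a diploid scoring: the first two recorded
#' fragment sizes, a single recorded size meaning a homozygote. Cells with no
#' recorded size are missing.
#'
#' @param tbl Genotype table (see [as_genotype_table()]).
#' @return Tibble `sample_id`, `locus`, `allele1`, `allele2` (both `NA` when
#'   missing), completed over every sample x locus combination.
#' @export
diploid_view <- function(tbl) {
  tbl <- as_genotype_table(tbl)
  tbl |>
    dplyr::mutate(
      allele1 = .data$a1,
      allele2 = dplyr::coalesce(.data$a2, .data$a1)
    ) |>
    dplyr::select("sample_id", "locus", "allele1", "allele2") |>
    tidyr::complete(
      sample_id = sample_order(tbl),
      locus = locus_order(tbl)
    ) |>
    dplyr::arrange(match(.data$sample_id, sample_order(tbl)),
                   match(.data$locus, locus_order(tbl)))
}

#' Allele frequencies per locus
#'
#' Frequencies over the diploid view: each non-missing individual contributes
#' two allele copies.
#'
#' @param tbl Genotype table.
#' @param loci Optional character vector restricting the loci.
#' @return Tibble `locus`, `allele` (fragment size in bp), `count`, `freq`;
#'   frequencies sum to 1 within each locus.
#' @export
allele_freqs <- function(tbl, loci = NULL) {
  dv <- diploid_view(tbl)
  if (!is.null(loci)) dv <- dplyr::filter(dv, .data$locus %in% loci)
  all_missing <- dv |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(ok = any(!is.na(.data$allele1)), .groups = "drop")
  if (any(!all_missing$ok)) {
    stop("no genotypes recorded at locus: ",
         paste(all_missing$locus[!all_missing$ok], collapse = ", "),
         call. = FALSE)
  }
  dv |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::count(.data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

# per-locus power sums of allele frequencies
freq_moments <- function(tbl) {
  allele_freqs(tbl) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      na = dplyr::n(),
      sum_p2 = sum(.data$freq^2),
      sum_p4 = sum(.data$freq^4),
      shannon = -sum(.data$freq * log(.data$freq)),
      .groups = "drop"
    )
}

#' Per-locus diversity statistics
#'
#' For each locus with allele frequencies `p`: number of alleles
#' `Na = |{p > 0}|`, effective number of alleles `Ne = 1 / sum(p^2)`,
#' expected heterozygosity (Nei gene diversity) `He = 1 - sum(p^2)`,
#' observed heterozygosity `Ho` = fraction of non-missing individuals with
#' two distinct alleles, Shannon information index `I = -sum(p log p)`, and
#' polymorphic information content
#' `PIC = 1 - sum(p^2) - sum(p^2)^2 + sum(p^4)`.
#'
#' @param tbl Genotype table.
#' @param unbiased_he If `TRUE`, multiply He by `2n/(2n-1)` (small-sample
#'   correction); default `FALSE`, matching the usual PowerMarker-style
#'   reporting.
#' @return Tibble with one row per locus: `locus`, `n_typed`, `na`, `ne`,
#'   `ho`, `he`, `shannon`, `pic`.
#' @export
#' @examples
#' g <- tibble::tibble(sample_id = c("s1", "s2"), locus = "L1",
#'                     a1 = c(180L, 180L), a2 = c(184L, 184L),
#'                     a3 = NA_integer_, a4 = NA_integer_)
#' ssr_diversity(g)
ssr_diversity <- function(tbl, unbiased_he = FALSE) {
  dv <- diploid_view(tbl)
  ho <- dv |>
    dplyr::filter(!is.na(.data$allele1)) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_typed = dplyr::n(),
      ho = mean(.data$allele1 != .data$allele2),
      .groups = "drop"
    )
  freq_moments(tbl) |>
    dplyr::left_join(ho, by = "locus") |>
    dplyr::mutate(
      ne = 1 / .data$sum_p2,
      he = 1 - .data$sum_p2,
      he = if (unbiased_he) .data$he * 2 * .data$n_typed / (2 * .data$n_typed - 1) else .data$he,
      pic = 1 - .data$sum_p2 - .data$sum_p2^2 + .data$sum_p4
    ) |>
    dplyr::arrange(match(.data$locus, locus_order(as_genotype_table(tbl)))) |>
    dplyr::select("locus", "n_typed", "na", "ne", "ho", "he", "shannon", "pic")
}

#' Panel-level summary of per-locus diversity statistics
#'
#' Unweighted arithmetic means over loci, plus the total allele count.
#'
#' @param div Per-locus tibble from [ssr_diversity()] (any tibble with
#'   columns `na`, `ne`, `he`, `pic` and optionally `ho`, `shannon` works,
#'   so published per-locus tables can be aggregated the same way).
#' @return One-row tibble: `n_loci`, `total_alleles`, `mean_na`, `mean_ne`,
#'   `mean_ho`, `mean_he`, `mean_shannon`, `mean_pic` (missing inputs give
#'   `NA` means).
#' @export
summarize_panel <- function(div) {
  grab <- function(col) if (col %in% names(div)) mean(div[[col]]) else NA_real_
  tibble::tibble(
    n_loci = nrow(div),
    total_alleles = sum(div$na),
    mean_na = mean(div$na),
    mean_ne = grab("ne"),
    mean_ho = grab("ho"),
    mean_he = grab("he"),
    mean_shannon = grab("shannon"),
    mean_pic = grab("pic")
  )
}

#' Probability-of-identity statistics per locus
#'
#' `PI` is the probability that two random unrelated individuals share a
#' genotype at the locus under Hardy-Weinberg proportions,
#' `PI = 2 (sum p^2)^2 - sum p^4`; `PIsibs` is the analogous probability for
#' full siblings,
#' `PIsibs = 0.25 + 0.5 sum p^2 + 0.5 (sum p^2)^2 - 0.25 sum p^4`.
#' Cumulative products are taken over loci ordered by ascending PI (most
#' informative first), giving the discriminating power of growing marker
#' combinations.
#'
#' @param tbl Genotype table.
#' @param order `"pi"` (ascending PI, default) or `"input"` (table order) for
#'   the cumulative products.
#' @return Tibble: `locus`, `pi`, `pi_sibs`, `rank`, `cum_pi`, `cum_pi_sibs`,
#'   sorted in cumulative order.
#' @export
ssr_identity <- function(tbl, order = c("pi", "input")) {
  order <- match.arg(order)
  m <- freq_moments(tbl) |>
    dplyr::mutate(
      pi = 2 * .data$sum_p2^2 - .data$sum_p4,
      pi_sibs = 0.25 + 0.5 * .data$sum_p2 + 0.5 * .data$sum_p2^2 -
        0.25 * .data$sum_p4
    ) |>
    dplyr::arrange(match(.data$locus, locus_order(as_genotype_table(tbl))))
  if (order == "pi") m <- dplyr::arrange(m, .data$pi)
  m |>
    dplyr::mutate(rank = dplyr::row_number(),
                  cum_pi = cumprod(.data$pi),
                  cum_pi_sibs = cumprod(.data$pi_sibs)) |>
    dplyr::select("locus", "pi", "pi_sibs", "rank", "cum_pi", "cum_pi_sibs")
}

# per-individual diploid genotype strings, individuals x loci matrix
genotype_string_matrix <- function(tbl) {
  dv <- diploid_view(tbl)
  dv |>
    dplyr::mutate(g = ifelse(
      is.na(.data$allele1), NA_character_,
      paste(pmin(.data$allele1, .data$allele2),
            pmax(.data$allele1, .data$allele2), sep = "/")
    )) |>
    dplyr::select("sample_id", "locus", "g") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "g") |>
    tibble::column_to_rownames("sample_id") |>
    as.matrix()
}

#' Find pairs of individuals with identical multilocus genotypes
#'
#' Two individuals match when their unordered diploid genotypes agree at
#' every locus where both are typed, and they share at least one typed locus.
#'
#' @param tbl Genotype table.
#' @return Tibble `sample_1`, `sample_2`, `n_compared` (loci typed in both);
#'   zero rows when all individuals are distinguishable.
#' @export
multilocus_match <- function(tbl) {
  gm <- genotype_string_matrix(tbl)
  ids <- rownames(gm)
  n <- length(ids)
  out <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq((i + 1L), n)) {
      both <- !is.na(gm[i, ]) & !is.na(gm[j, ])
      if (any(both) && all(gm[i, both] == gm[j, both])) {
        out[[length(out) + 1L]] <- tibble::tibble(
          sample_1 = ids[i], sample_2 = ids[j], n_compared = sum(both)
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(sample_1 = character(), sample_2 = character(),
                          n_compared = integer()))
  }
  dplyr::bind_rows(out)
}

#' Pairwise genetic similarity from band presence/absence
#'
#' Alleles are expanded to a binary band-presence profile (one band per
#' locus-allele, from the diploid view). For a pair of individuals only bands
#' at loci typed in both are compared: `a` bands shared present, `d` shared
#' absent, `b`/`c` present in one only. Simple matching is `(a+d)/(a+b+c+d)`,
#' Dice is `2a/(2a+b+c)`.
#'
#' @param tbl Genotype table.
#' @param coefficient `"simple_matching"` (default) or `"dice"`.
#' @return Square symmetric numeric matrix with unit diagonal, dimnames =
#'   sample ids.
#' @export
gs_matrix <- function(tbl, coefficient = c("simple_matching", "dice")) {
  coefficient <- match.arg(coefficient)
  dv <- diploid_view(tbl)
  ids <- sample_order(tbl)
  bands <- allele_freqs(tbl) |>
    dplyr::transmute(band = paste(.data$locus, .data$allele, sep = ":"),
                     locus = .data$locus)
  long <- dv |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::distinct(.data$sample_id, .data$locus, .data$allele) |>
    dplyr::mutate(band = paste(.data$locus, .data$allele, sep = ":"))
  p <- matrix(0, nrow = length(ids), ncol = nrow(bands),
              dimnames = list(ids, bands$band))
  p[cbind(long$sample_id, long$band)] <- 1
  # typed mask per band = typed at that band's locus
  typed <- dv |>
    dplyr::mutate(typed = !is.na(.data$allele1)) |>
    dplyr::select("sample_id", "locus", "typed") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "typed") |>
    tibble::column_to_rownames("sample_id") |>
    as.matrix()
  m <- typed[ids, bands$locus, drop = FALSE] * 1
  q <- m - p  # typed-and-absent
  a <- tcrossprod(p)
  d <- tcrossprod(q)
  b <- tcrossprod(p, q)
  cc <- tcrossprod(q, p)
  gs <- if (coefficient == "simple_matching") {
    (a + d) / (a + b + cc + d)
  } else {
    2 * a / (2 * a + b + cc)
  }
  diag(gs) <- 1
  gs
}

#' Genetic distance matrix from a similarity matrix
#'
#' @param gs Similarity matrix from [gs_matrix()].
#' @return `1 - gs`, zero diagonal.
#' @export
genetic_dist <- function(gs) {
  d <- 1 - gs
  diag(d) <- 0
  d
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords Tibble with `sample_id`, `lat`, `lon` in decimal degrees.
#' @return Square symmetric matrix of distances in km.
#' @export
geo_distance <- function(coords) {
  stopifnot(all(c("sample_id", "lat", "lon") %in% names(coords)))
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180)) {
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180", call. = FALSE)
  }
  p <- cbind(coords$lon, coords$lat)
  d <- geosphere::distm(p, fun = function(x, y) {
    geosphere::distHaversine(x, y, r = 6371000)
  }) / 1000
  dimnames(d) <- list(coords$sample_id, coords$sample_id)
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with a one-sided
#' permutation p-value `(1 + #{r_perm >= r_obs}) / (n_perm + 1)` obtained by
#' jointly permuting rows and columns of the second matrix.
#'
#' @param d1,d2 Square symmetric matrices with zero diagonal and identical
#'   dimnames order (e.g. genetic and geographic distances).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutations.
#' @return An object of class `ssr_mantel` with elements `r`, `p`, `n_perm`,
#'   `n`, `seed`; [generics::glance()] returns it as a one-row tibble.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999L, seed = 1L) {
  stopifnot(nrow(d1) == ncol(d1), nrow(d2) == ncol(d2),
            nrow(d1) == nrow(d2))
  if (!is.null(dimnames(d1)) && !is.null(dimnames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("matrix orders differ; reorder one matrix to match the other",
         call. = FALSE)
  }
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  r_obs <- stats::cor(v1, d2[lt])
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    o <- sample.int(n)
    stats::cor(v1, d2[o, o][lt])
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  structure(list(r = r_obs, p = p, n_perm = as.integer(n_perm), n = n,
                 seed = seed),
            class = "ssr_mantel")
}

#' @export
print.ssr_mantel <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

#' @export
glance.ssr_mantel <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, n_perm = x$n_perm, n = x$n, seed = x$seed)
}

#' @export
tidy.ssr_mantel <- function(x, ...) glance(x)

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition. Axes
#' with positive eigenvalues are retained; percent variance is each positive
#' eigenvalue over their sum. Axis signs are fixed by making the
#' largest-magnitude score on each axis positive, so results are
#' reproducible across platforms.
#'
#' @param d Square symmetric distance matrix with zero diagonal.
#' @param correction `"none"` (default) or `"lingoes"` (adds the constant
#'   that makes all eigenvalues non-negative when negative eigenvalues
#'   appear).
#' @return Object of class `ssr_pcoa`: `scores` (tibble, `sample_id` +
#'   `axis1..axisM`), `eig` (positive eigenvalues), `pct_var`.
#'   [generics::tidy()] returns the scores.
#' @export
pcoa_dist <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(d)
  ids <- rownames(d) %||% paste0("s", seq_len(n))
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% a %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  if (correction == "lingoes" && min(e$values) < -1e-8) {
    cstar <- -min(e$values)
    d2 <- sqrt(d^2 + 2 * cstar)
    diag(d2) <- 0
    return(pcoa_dist(d2, correction = "none"))
  }
  pos <- which(e$values > 1e-8 * max(abs(e$values)))
  lam <- e$values[pos]
  v <- e$vectors[, pos, drop = FALSE]
  scores <- sweep(v, 2, sqrt(lam), `*`)
  for (k in seq_along(pos)) {
    if (scores[which.max(abs(scores[, k])), k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("axis", seq_along(pos))
  structure(list(
    scores = tibble::tibble(sample_id = ids) |>
      dplyr::bind_cols(tibble::as_tibble(scores)),
    eig = lam,
    pct_var = 100 * lam / sum(lam)
  ), class = "ssr_pcoa")
}

#' @export
print.ssr_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d positive axes; first axes explain %s%%\n",
              length(x$eig),
              paste(sprintf("%.1f", utils::head(x$pct_var, 3)), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.ssr_pcoa <- function(x, ...) x$scores

#' @export
glance.ssr_pcoa <- function(x, ...) {
  tibble::tibble(n_axes = length(x$eig),
                 pct_var_axis1 = x$pct_var[1],
                 pct_var_axis2 = if (length(x$pct_var) > 1) x$pct_var[2] else NA_real_)
}

#' Distance tree of individuals
#'
#' UPGMA (average-linkage agglomeration) or neighbour-joining on a distance
#' matrix. Rows are sorted lexicographically by label first so ties resolve
#' deterministically.
#'
#' @param d Square symmetric distance matrix with dimnames.
#' @param method `"upgma"` or `"nj"`.
#' @return An [ape::phylo] tree with branch lengths.
#' @export
build_tree <- function(d, method = c("upgma", "nj")) {
  method <- match.arg(method)
  if (nrow(d) < 3L) stop("need at least 3 taxa", call. = FALSE)
  o <- order(rownames(d))
  d <- d[o, o]
  if (method == "upgma") {
    h <- stats::hclust(stats::as.dist(d), method = "average")
    tr <- ape::as.phylo(h)
    tr$edge.length <- tr$edge.length  # heights halved by as.phylo already
    tr
  } else {
    ape::nj(stats::as.dist(d))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
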