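#' Zygosity fingerprint encoding
#'
#' The gel-reading style code: one digit per (individual, locus) — `9` for a
#' missing genotype, `0` for a heterozygote (two distinct sizes), `1` for a
#' homozygote.
#'
#' @param tbl Genotype table.
#' @return Tibble `sample_id`, `scheme` (`"zygosity"`), `code` (one digit per
#'   locus, in locus order); attribute `loci` records the locus order.
#' @export
#' @examples
#' g <- tibble::tibble(sample_id = "s1", locus = c("L1", "L2"),
#'                     a1 = c(180L, 200L), a2 = c(184L, NA),
#'                     a3 = NA_integer_, a4 = NA_integer_)
#' encode_zygosity(g)$code  # "01"
encode_zygosity <- function(tbl) {
  loci <- locus_order(as_genotype_table(tbl))
  codes <- diploid_view(tbl) |>
    dplyr::mutate(digit = dplyr::case_when(
      is.na(.data$allele1) ~ "9",
      .data$allele1 != .data$allele2 ~ "0",
      TRUE ~ "1"
    )) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      code = paste(.data$digit[match(loci, .data$locus)], collapse = ""),
      .groups = "drop"
    ) |>
    dplyr::mutate(scheme = "zygosity", .after = "sample_id") |>
    dplyr::arrange(match(.data$sample_id, sample_order(as_genotype_table(tbl))))
  attr(codes, "loci") <- loci
  codes
}

#' Fragment-size bin scheme for the bin fingerprint encoding
#'
#' Each locus's fragment-size range is cut into 10-bp bins numbered 1-9,
#' anchored at the minimum observed size (or an explicit start); sizes past
#' the ninth bin fold into bin 9, missing records code as 0.
#'
#' @param tbl Genotype table (used to find per-locus minimum sizes).
#' @param bin_width Bin width in bp (default 10).
#' @param starts Optional tibble `locus`, `start_bp` overriding the observed
#'   minima.
#' @return Tibble `locus`, `start_bp`, `bin_width`.
#' @export
bin_scheme <- function(tbl, bin_width = 10L, starts = NULL) {
  tbl <- as_genotype_table(tbl)
  sc <- tbl |>
    tidyr::pivot_longer(c("a1", "a2", "a3", "a4"), values_to = "size") |>
    dplyr::filter(!is.na(.data$size)) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(start_bp = min(.data$size), .groups = "drop") |>
    dplyr::mutate(bin_width = as.integer(bin_width)) |>
    dplyr::arrange(match(.data$locus, locus_order(tbl)))
  if (!is.null(starts)) {
    sc <- sc |>
      dplyr::rows_update(dplyr::select(starts, "locus", "start_bp"),
                         by = "locus")
  }
  sc
}

bin_digit <- function(size, start, width) {
  pmin(9L, 1L + (size - start) %/% width)
}

#' Bin fingerprint encoding
#'
#' Per locus, up to four recorded allele sizes are encoded in ascending
#' order as bin digits (1-9; see [bin_scheme()]); absent third/fourth
#' records pad with 0 and a fully missing cell codes as `0000`.
#'
#' @param tbl Genotype table.
#' @param scheme A [bin_scheme()] tibble (built from `tbl` if omitted).
#' @return Tibble `sample_id`, `scheme` (`"bins"`), `code` (four digits per
#'   locus, in locus order); attribute `loci` records the locus order.
#' @export
encode_bins <- function(tbl, scheme = NULL) {
  tbl <- as_genotype_table(tbl)
  if (is.null(scheme)) scheme <- bin_scheme(tbl)
  loci <- locus_order(tbl)
  long <- tbl |>
    tidyr::complete(sample_id = sample_order(tbl), locus = loci) |>
    dplyr::left_join(scheme, by = "locus")
  miss <- long |>
    tidyr::pivot_longer(c("a1", "a2", "a3", "a4"), values_to = "size") |>
    dplyr::filter(!is.na(.data$size), .data$size < .data$start_bp)
  if (nrow(miss) > 0L) {
    stop("fragment size below bin-scheme start at locus ",
         paste(unique(miss$locus), collapse = ", "), call. = FALSE)
  }
  group_code <- function(a1, a2, a3, a4, start, width) {
    sizes <- sort(c(a1, a2, a3, a4))
    digits <- c(bin_digit(sizes, start, width), rep(0L, 4L - length(sizes)))
    paste(digits, collapse = "")
  }
  codes <- long |>
    dplyr::mutate(group = purrr::pmap_chr(
      list(.data$a1, .data$a2, .data$a3, .data$a4,
           .data$start_bp, .data$bin_width), group_code
    )) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      code = paste(.data$group[match(loci, .data$locus)], collapse = ""),
      .groups = "drop"
    ) |>
    dplyr::mutate(scheme = "bins", .after = "sample_id") |>
    dplyr::arrange(match(.data$sample_id, sample_order(tbl)))
  attr(codes, "loci") <- loci
  codes
}

#' Groups of individuals with identical fingerprint codes
#'
#' @param codes Tibble from [encode_zygosity()] / [encode_bins()].
#' @return Tibble `code`, `n`, `sample_ids` (list-column), one row per group
#'   of two or more; zero rows means every individual is distinguishable.
#' @export
check_distinguishable <- function(codes) {
  codes |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(n = dplyr::n(),
                     sample_ids = list(.data$sample_id), .groups = "drop") |>
    dplyr::filter(.data$n > 1L)
}

# per-locus code fragments, individuals x loci character matrix
fragment_matrix <- function(tbl, scheme_name, bins = NULL) {
  tbl <- as_genotype_table(tbl)
  loci <- locus_order(tbl)
  ids <- sample_order(tbl)
  if (scheme_name == "zygosity") {
    dv <- diploid_view(tbl) |>
      dplyr::mutate(frag = dplyr::case_when(
        is.na(.data$allele1) ~ "9",
        .data$allele1 != .data$allele2 ~ "0",
        TRUE ~ "1"
      ))
  } else {
    if (is.null(bins)) bins <- bin_scheme(tbl)
    dv <- tbl |>
      tidyr::complete(sample_id = ids, locus = loci) |>
      dplyr::left_join(bins, by = "locus") |>
      dplyr::mutate(frag = purrr::pmap_chr(
        list(.data$a1, .data$a2, .data$a3, .data$a4,
             .data$start_bp, .data$bin_width),
        function(a1, a2, a3, a4, start, width) {
          sizes <- sort(c(a1, a2, a3, a4))
          paste(c(bin_digit(sizes, start, width),
                  rep(0L, 4L - length(sizes))), collapse = "")
        }
      ))
  }
  m <- dv |>
    dplyr::select("sample_id", "locus", "frag") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "frag") |>
    tibble::column_to_rownames("sample_id")
  as.matrix(m)[ids, loci, drop = FALSE]
}

all_singletons <- function(m, cols) {
  keys <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
  !anyDuplicated(keys)
}

#' Minimal discriminating marker subset
#'
#' Finds a small subset of loci whose fingerprint codes still distinguish
#' every individual. `greedy` iteratively adds the locus that maximally
#' splits the remaining identical groups (ties by locus order); `exhaustive`
#' searches subset sizes breadth-first and returns a provably minimal subset
#' (restricted to panels of at most 12 loci).
#'
#' @param tbl Genotype table.
#' @param scheme `"bins"` (default) or `"zygosity"`.
#' @param strategy `"greedy"` (default) or `"exhaustive"`.
#' @param bins Optional [bin_scheme()] override.
#' @return Character vector of locus ids (a discriminating subset).
#' @export
min_discriminating_set <- function(tbl, scheme = c("bins", "zygosity"),
                                   strategy = c("greedy", "exhaustive"),
                                   bins = NULL) {
  scheme <- match.arg(scheme)
  strategy <- match.arg(strategy)
  m <- fragment_matrix(tbl, scheme, bins)
  loci <- colnames(m)
  if (!all_singletons(m, loci)) {
    keys <- apply(m, 1, paste, collapse = "")
    dup <- split(rownames(m), keys)
    dup <- dup[lengths(dup) > 1]
    stop("full panel cannot distinguish: ",
         paste(vapply(dup, paste, "", collapse = "="), collapse = "; "),
         call. = FALSE)
  }
  if (strategy == "exhaustive") {
    if (length(loci) > 12L) {
      stop("exhaustive search is restricted to <= 12 loci", call. = FALSE)
    }
    for (size in seq_along(loci)) {
      subs <- utils::combn(loci, size, simplify = FALSE)
      for (s in subs) if (all_singletons(m, s)) return(s)
    }
  }
  chosen <- character(0)
  repeat {
    if (length(chosen) > 0 && all_singletons(m, chosen)) break
    remaining <- setdiff(loci, chosen)
    n_groups <- vapply(remaining, function(l) {
      length(unique(apply(m[, c(chosen, l), drop = FALSE], 1,
                          paste, collapse = "")))
    }, numeric(1))
    chosen <- c(chosen, remaining[which.max(n_groups)])
  }
  chosen
}
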