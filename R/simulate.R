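#' Simulate a genome with planted SSR ground truth
#'
#' Builds background sequence with independent bases at a stated GC content,
#' scrubbed of accidental above-threshold SSRs by rejection (found loci are
#' redrawn, up to an iteration cap), then overwrites windows with planted
#' perfect SSRs of known motif, repeat count and position. Planted positions
#' can be biased toward chromosome ends (the pattern seen in real grass
#' genomes); planted loci are separated by more than the compound gap so the
#' truth table round-trips exactly through [find_ssrs()].
#'
#' Defaults emulate a desk-scale version of a large grass genome scan: two
#' 100-kb chromosomes, 124 loci/Mb, mono- to hexanucleotide classes weighted
#' 43.3/35.1/20.2/0.9/0.2/0.3% and repeat counts a few units above the
#' mining thresholds.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp (>= 10 kb).
#' @param rate_per_mb Planted SSR density, loci/Mb (default 124).
#' @param unit_weights Sampling weights for motif length 1-6.
#' @param extra_repeats_mean Mean number of repeat units above the mining
#'   threshold (geometric, default 3).
#' @param end_bias Strength of the edge-proximity position bias (0 =
#'   uniform; density is proportional to `1 + end_bias * proximity` with
#'   proximity 0 at the midpoint and 1 at the ends).
#' @param gc Background GC fraction (default 0.46).
#' @param params [ssr_search_params()] the planted loci must satisfy.
#' @param seed Integer seed.
#' @param max_reject Iteration cap for the background-scrubbing loop.
#' @return Object of class `planted_genome`: `sequences` (named character),
#'   `truth` (locus tibble in [find_ssrs()] layout), `params`.
#' @export
simulate_genome <- function(chrom_lengths = c(chr1 = 100000L, chr2 = 100000L),
                            rate_per_mb = 124,
                            unit_weights = c(43.3, 35.1, 20.2, 0.9, 0.2, 0.3),
                            extra_repeats_mean = 3,
                            end_bias = 1,
                            gc = 0.46,
                            params = ssr_search_params(),
                            seed = 1L,
                            max_reject = 50L) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 10000),
            rate_per_mb >= 0, length(unit_weights) == 6L)
  set.seed(seed)
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- names(base_probs)
  gap <- params$compound_gap_bp

  draw_background <- function(len) {
    s <- paste(sample(bases, len, replace = TRUE, prob = base_probs),
               collapse = "")
    for (it in seq_len(max_reject)) {
      found <- find_ssrs(s, chrom = "bg", params = params)
      if (nrow(found) == 0L) return(s)
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      for (i in seq_len(nrow(found))) {
        idx <- found$start[i]:found$end[i]
        chars[idx] <- sample(bases, length(idx), replace = TRUE,
                             prob = base_probs)
      }
      s <- paste(chars, collapse = "")
    }
    stop("could not scrub accidental SSRs from background within the cap",
         call. = FALSE)
  }

  random_primitive_motif <- function(k) {
    repeat {
      m <- paste(sample(bases, k, replace = TRUE), collapse = "")
      if (is_primitive_motif(m)) return(m)
    }
  }

  plant_one_chrom <- function(len, chrom) {
    n_plant <- stats::rpois(1, rate_per_mb * len / 1e6)
    s <- draw_background(len)
    if (n_plant == 0L) {
      return(list(seq = s, truth = NULL))
    }
    units <- sample(1:6, n_plant, replace = TRUE, prob = unit_weights)
    n_rep <- params$min_repeats[units] +
      stats::rgeom(n_plant, 1 / (1 + extra_repeats_mean))
    span <- units * n_rep
    max_span <- max(span)
    need <- sum(span) + (n_plant + 1L) * (gap + 1L)
    if (need > len) {
      stop("infeasible packing: planted SSRs plus spacing exceed chromosome length",
           call. = FALSE)
    }
    # positions with edge bias, re-drawn until mutually compatible
    margin <- gap + 2L
    for (attempt in seq_len(max_reject)) {
      u <- stats::runif(n_plant)
      w <- stats::runif(n_plant)
      # accept-reject against density 1 + bias * proximity(2|x-0.5|)
      keepers <- w <= (1 + end_bias * 2 * abs(u - 0.5)) / (1 + end_bias)
      while (!all(keepers)) {
        u[!keepers] <- stats::runif(sum(!keepers))
        w <- stats::runif(n_plant)
        keepers <- keepers | w <= (1 + end_bias * 2 * abs(u - 0.5)) / (1 + end_bias)
      }
      starts <- sort(round(margin + u * (len - 2L * margin - max_span)))
      o <- order(starts)
      st <- starts[o]; sp <- span[o]
      ends <- st + sp - 1L
      if (all(diff(st) - sp[-n_plant] > gap)) {
        units <- units[o]; n_rep <- n_rep[o]
        break
      }
      if (attempt == max_reject) {
        stop("infeasible packing: could not place planted SSRs with the required spacing",
             call. = FALSE)
      }
    }
    motifs <- vapply(units, random_primitive_motif, character(1))
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_len(n_plant)) {
      run <- strsplit(strrep(motifs[i], n_rep[i]), "", fixed = TRUE)[[1]]
      chars[st[i]:ends[i]] <- run
      # block single-base extension of the run and unit-length joins
      before <- st[i] - 1L
      after <- ends[i] + 1L
      if (before >= 1L) {
        avoid <- c(run[length(run)], substr(motifs[i], units[i], units[i]))
        chars[before] <- sample(setdiff(bases, avoid), 1)
      }
      if (after <= len) {
        avoid <- c(run[1], substr(motifs[i], 1L + (n_rep[i] * units[i]) %% units[i], 1L + (n_rep[i] * units[i]) %% units[i]))
        chars[after] <- sample(setdiff(bases, c(avoid, run[1])), 1)
      }
    }
    seqo <- paste(chars, collapse = "")
    truth <- tibble::tibble(
      chrom = chrom, start = as.integer(st), end = as.integer(ends),
      motif = motifs, canonical_motif = canonical_motif(motifs),
      unit_length = as.integer(units), n_repeats = as.integer(n_rep),
      length_bp = as.integer(sp), length_class = classify_length(sp),
      compound_id = NA_character_
    )
    list(seq = seqo, truth = truth)
  }

  built <- purrr::imap(as.list(chrom_lengths), function(len, ch) {
    plant_one_chrom(as.integer(len), ch)
  })
  sequences <- purrr::map_chr(built, "seq")
  empty_truth <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    motif = character(), canonical_motif = character(),
    unit_length = integer(), n_repeats = integer(), length_bp = integer(),
    length_class = character(), compound_id = character()
  )
  truth <- dplyr::bind_rows(c(list(empty_truth),
                              unname(purrr::map(built, "truth"))))
  # final verification: the miner must reproduce the truth exactly; if local
  # edits created a stray locus, scrub it and re-check (bounded loop)
  for (it in seq_len(max_reject)) {
    mined <- find_ssrs_all(sequences, params = params)
    extra <- dplyr::anti_join(mined, truth,
                              by = c("chrom", "start", "end", "motif"))
    if (nrow(extra) == 0L && nrow(mined) == nrow(truth)) break
    for (i in seq_len(nrow(extra))) {
      ch <- extra$chrom[i]
      chars <- strsplit(sequences[[ch]], "", fixed = TRUE)[[1]]
      idx <- extra$start[i]:extra$end[i]
      # only redraw bases not inside a planted locus
      tch <- dplyr::filter(truth, .data$chrom == ch)
      planted <- unlist(purrr::map2(tch$start, tch$end, seq))
      idx <- setdiff(idx, planted)
      chars[idx] <- sample(bases, length(idx), replace = TRUE,
                           prob = base_probs)
      sequences[[ch]] <- paste(chars, collapse = "")
    }
    if (it == max_reject) {
      stop("could not reconcile mined loci with the planted truth", call. = FALSE)
    }
  }
  structure(list(
    sequences = sequences,
    truth = dplyr::arrange(truth, match(.data$chrom, names(chrom_lengths)),
                           .data$start),
    params = list(chrom_lengths = chrom_lengths, rate_per_mb = rate_per_mb,
                  unit_weights = unit_weights,
                  extra_repeats_mean = extra_repeats_mean,
                  end_bias = end_bias, gc = gc, search = params, seed = seed)
  ), class = "planted_genome")
}

#' @export
print.planted_genome <- function(x, ...) {
  cat(sprintf("Planted genome: %d sequence(s), %s bp, %d planted SSRs\n",
              length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ","),
              nrow(x$truth)))
  invisible(x)
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a structured diploid genotype panel
#'
#' Generates a fragment-size genotype panel from K ancestral clusters: per
#' cluster and locus, allele frequencies over a size ladder are Dirichlet;
#' each individual's admixture proportions are Dirichlet(`alpha`); the two
#' allele copies per locus are drawn independently through the admixture
#' mixture; genotypes go missing completely at random. Coordinates are
#' cluster centres plus noise when isolation-by-distance is on (so genetic
#' and geographic distances correlate), uniform otherwise.
#'
#' Defaults emulate a 105-accession, 20-marker steppe-grass diversity panel
#' with four ancestral clusters and highly polymorphic loci.
#'
#' @param n Individuals (default 105).
#' @param n_loci Loci (default 20).
#' @param K Ancestral clusters (default 4).
#' @param alpha Dirichlet concentration for admixture proportions (scalar,
#'   default 0.2: most individuals dominated by one cluster).
#' @param n_alleles Alleles on each locus ladder (default 25).
#' @param freq_conc Dirichlet concentration per allele for cluster frequency
#'   profiles (default 0.3; smaller = more cluster differentiation).
#' @param ladder_base Range of locus minimum fragment sizes in bp
#'   (default c(100, 240)).
#' @param ladder_step Size step between adjacent ladder alleles in bp
#'   (default 2, dinucleotide motifs).
#' @param missing_rate Probability a genotype is missing (default 0.02).
#' @param ibd Isolation by distance: `TRUE` places individuals near their
#'   dominant cluster's geographic centre.
#' @param coord_noise_sd SD in degrees of the coordinate noise around
#'   cluster centres (default 1).
#' @param seed Integer seed.
#' @return Object of class `simulated_panel`: `genotypes` (genotype table),
#'   `q_true` (tibble `sample_id`, `k1..kK`), `freqs_true` (tibble `locus`,
#'   `allele`, `k1..kK` frequencies), `coords` (tibble `sample_id`, `lat`,
#'   `lon`), `params`.
#' @export
simulate_panel <- function(n = 105L, n_loci = 20L, K = 4L, alpha = 0.2,
                           n_alleles = 25L, freq_conc = 0.3,
                           ladder_base = c(100, 240), ladder_step = 2L,
                           missing_rate = 0.02, ibd = TRUE,
                           coord_noise_sd = 1, seed = 1L) {
  stopifnot(n >= K, K >= 1, n_loci >= 1, n_alleles >= 2,
            missing_rate >= 0, missing_rate < 1, alpha > 0, freq_conc > 0)
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n))
  loci <- sprintf("M%02d", seq_len(n_loci))
  ladders <- purrr::map(seq_len(n_loci), function(l) {
    base <- sample(seq(ladder_base[1], ladder_base[2]), 1)
    as.integer(base + ladder_step * (seq_len(n_alleles) - 1L))
  })
  freqs <- purrr::map(seq_len(n_loci), function(l) {
    t(rdirichlet(K, rep(freq_conc, n_alleles)))  # alleles x K
  })
  q <- rdirichlet(n, rep(alpha, K))
  draw_copy <- function(i, l) {
    k <- sample.int(K, 1, prob = q[i, ])
    sample(ladders[[l]], 1, prob = freqs[[l]][, k])
  }
  geno <- tidyr::expand_grid(ind = seq_len(n), loc = seq_len(n_loci)) |>
    dplyr::mutate(
      c1 = purrr::map2_int(.data$ind, .data$loc, draw_copy),
      c2 = purrr::map2_int(.data$ind, .data$loc, draw_copy),
      missing = stats::runif(dplyr::n()) < missing_rate,
      a1 = ifelse(.data$missing, NA_integer_, pmin(.data$c1, .data$c2)),
      a2 = ifelse(.data$missing, NA_integer_, pmax(.data$c1, .data$c2)),
      a2 = ifelse(.data$a1 == .data$a2, NA_integer_, .data$a2)
    ) |>
    dplyr::transmute(
      sample_id = ids[.data$ind], locus = loci[.data$loc],
      a1 = .data$a1, a2 = .data$a2,
      a3 = NA_integer_, a4 = NA_integer_
    )
  # geography: cluster centres across a steppe-like map window
  centers <- cbind(lat = stats::runif(K, 40, 50),
                   lon = stats::runif(K, 105, 125))
  if (ibd) {
    dominant <- max.col(q)
    coords <- tibble::tibble(
      sample_id = ids,
      lat = centers[dominant, "lat"] + stats::rnorm(n, 0, coord_noise_sd),
      lon = centers[dominant, "lon"] + stats::rnorm(n, 0, coord_noise_sd)
    )
  } else {
    coords <- tibble::tibble(
      sample_id = ids,
      lat = stats::runif(n, 40, 50),
      lon = stats::runif(n, 105, 125)
    )
  }
  q_tb <- tibble::tibble(sample_id = ids) |>
    dplyr::bind_cols(tibble::as_tibble(q, .name_repair = ~ paste0("k", seq_len(K))))
  f_tb <- purrr::map2(seq_len(n_loci), freqs, function(l, fm) {
    colnames(fm) <- paste0("k", seq_len(K))
    tibble::tibble(locus = loci[l], allele = ladders[[l]]) |>
      dplyr::bind_cols(tibble::as_tibble(fm))
  }) |> dplyr::bind_rows()
  structure(list(
    genotypes = geno, q_true = q_tb, freqs_true = f_tb, coords = coords,
    params = list(n = n, n_loci = n_loci, K = K, alpha = alpha,
                  n_alleles = n_alleles, freq_conc = freq_conc,
                  ladder_base = ladder_base, ladder_step = ladder_step,
                  missing_rate = missing_rate, ibd = ibd,
                  coord_noise_sd = coord_noise_sd, seed = seed)
  ), class = "simulated_panel")
}

#' @export
print.simulated_panel <- function(x, ...) {
  p <- x$params
  cat(sprintf("Simulated panel: %d individuals x %d loci, K = %d, missing %.1f%%%s\n",
              p$n, p$n_loci, p$K, 100 * p$missing_rate,
              if (p$ibd) ", isolation by distance" else ""))
  invisible(x)
}
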