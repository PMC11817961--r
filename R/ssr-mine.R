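#' Search parameters for SSR detection
#'
#' MISA-style minimum full-unit repeat counts per motif length, plus the gap
#' below which neighbouring loci are annotated as a compound SSR.
#'
#' @param min_repeats Integer vector of length 6: minimum number of complete
#'   repeat units for mono- through hexanucleotide motifs. Defaults to the
#'   common plant-genome setting 10, 6, 5, 5, 5, 5.
#' @param compound_gap_bp Maximum number of intervening bases for two SSRs to
#'   be annotated as parts of one compound SSR (default 100).
#'
#' @return A list of class `ssr_search_params`.
#' @export
#' @examples
#' ssr_search_params()
ssr_search_params <- function(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                              compound_gap_bp = 100L) {
  min_repeats <- as.integer(min_repeats)
  if (length(min_repeats) != 6L || anyNA(min_repeats) || any(min_repeats < 1L)) {
    stop("`min_repeats` must be six integers >= 1 (mono..hexa).", call. = FALSE)
  }
  compound_gap_bp <- as.integer(compound_gap_bp)
  if (is.na(compound_gap_bp) || compound_gap_bp < 0L) {
    stop("`compound_gap_bp` must be a non-negative integer.", call. = FALSE)
  }
  structure(list(min_repeats = min_repeats, compound_gap_bp = compound_gap_bp),
            class = "ssr_search_params")
}

# reverse complement of an ACGT string (vectorised)
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# TRUE if the motif is not a tandem repetition of a shorter unit
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L && strrep(substr(m, 1L, d), k / d) == m) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

cyclic_rotations <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(m)
  doubled <- paste0(m, m)
  vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L), character(1))
}

#' Canonical representative of a repeat-motif class
#'
#' Motifs are grouped into classes under cyclic rotation and reverse
#' complementation (so AG, GA, CT and TC all belong to one class). The class
#' representative is the lexicographically smallest string over all rotations
#' of the motif and of its reverse complement; this reproduces the usual
#' A/T, AG/CT, AAG/CTT, AGAT/ATCT labels.
#'
#' @param motif Character vector of primitive repeat units (1-6 bp, ACGT).
#' @return Character vector of canonical motifs, same length as `motif`.
#' @export
#' @examples
#' canonical_motif(c("CT", "T", "ATCT"))  # "AG" "A" "AGAT"
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  if (any(grepl("[^ACGT]", motif)) || any(!nzchar(motif)) || any(nchar(motif) > 6L)) {
    stop("motifs must be 1-6 bp over A/C/G/T", call. = FALSE)
  }
  bad <- !is_primitive_motif(motif)
  if (any(bad)) {
    stop("non-primitive motif(s): ", paste(unique(motif[bad]), collapse = ", "),
         call. = FALSE)
  }
  vapply(motif, function(m) {
    min(c(cyclic_rotations(m), cyclic_rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Count canonical repeat-motif classes for a motif length
#'
#' Enumerates all `4^k` motifs of length `unit_length`, drops those that are
#' tandem repetitions of a shorter unit, and counts the distinct canonical
#' classes under rotation + reverse complementation. For mono- to
#' hexanucleotides the counts are 2, 4, 10, 33, 102 and 350; a finite genome
#' need not realise every class for k >= 5.
#'
#' @param unit_length Motif length, 1-6.
#' @return Integer count of classes.
#' @export
#' @examples
#' enumerate_motif_classes(3)  # 10
#' enumerate_motif_classes(4)  # 33
enumerate_motif_classes <- function(unit_length) {
  unit_length <- as.integer(unit_length)
  if (length(unit_length) != 1L || is.na(unit_length) ||
      unit_length < 1L || unit_length > 6L) {
    stop("`unit_length` must be a single integer in 1..6", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  grids <- do.call(expand.grid, rep(list(bases), unit_length))
  motifs <- do.call(paste0, grids)
  motifs <- motifs[is_primitive_motif(motifs)]
  length(unique(canonical_motif(motifs)))
}

#' Length class of an SSR locus
#'
#' Class III loci are shorter than 20 nt, class II span 20-30 nt inclusive,
#' class I exceed 30 nt. Longer loci make more mutable, more polymorphic
#' markers, which is why the classes are tracked.
#'
#' @param length_bp Integer vector of total locus lengths in bp.
#' @return Character vector over `"I"`, `"II"`, `"III"`.
#' @export
classify_length <- function(length_bp) {
  if (any(length_bp < 1)) stop("length_bp must be >= 1", call. = FALSE)
  dplyr::case_when(
    length_bp < 20 ~ "III",
    length_bp <= 30 ~ "II",
    TRUE ~ "I"
  )
}

# scan one N-free uppercase segment; returns a list of locus data.frames
scan_segment <- function(seg, offset, min_repeats) {
  n <- nchar(seg)
  x <- utf8ToInt(seg)
  out <- vector("list", 6L)
  for (k in 1:6) {
    if (n < k * min_repeats[k]) next
    eq <- x[seq_len(n - k)] == x[seq_len(n - k) + k]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths + k) >= k * min_repeats[k]
    if (!any(keep)) next
    st <- starts[keep]
    reg_len <- r$lengths[keep] + k
    n_rep <- reg_len %/% k
    motif <- substring(seg, st, st + k - 1L)
    prim <- is_primitive_motif(motif)
    if (!any(prim)) next
    st <- st[prim]; n_rep <- n_rep[prim]; motif <- motif[prim]
    out[[k]] <- data.frame(
      start = offset + st,
      end = offset + st + n_rep * k - 1L,
      motif = motif,
      unit_length = k,
      n_repeats = n_rep,
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Detect perfect SSRs in a nucleotide sequence
#'
#' Finds every maximal perfect tandem run of a primitive 1-6 bp unit whose
#' complete-unit repeat count meets the per-unit-length threshold. A locus
#' covers only full repeat units: a trailing partial unit is excluded, so
#' `length_bp = unit_length * n_repeats` always holds. Ambiguous bases (N)
#' terminate runs; lowercase input is accepted. Runs reportable at a shorter
#' unit length are not re-reported at multiples of it (e.g. poly-A is never
#' also an "AA" dinucleotide locus).
#'
#' @param sequence A single nucleotide string over A/C/G/T/N (case
#'   insensitive).
#' @param chrom Sequence identifier recorded in the output.
#' @param params An [ssr_search_params()] object.
#' @return A tibble with one row per locus: `chrom`, `start`, `end` (1-based
#'   inclusive), `motif` (as on the forward strand), `canonical_motif`,
#'   `unit_length`, `n_repeats`, `length_bp`, `length_class`, `compound_id`
#'   (`NA`; see [annotate_compound()]), sorted by `start`.
#' @export
#' @examples
#' find_ssrs("GGACACACACACACGG", chrom = "chr1")
find_ssrs <- function(sequence, chrom = "seq", params = ssr_search_params()) {
  stopifnot(length(sequence) == 1L)
  seq_up <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", seq_up)
  if (bad > 0L) {
    stop(sprintf("non-nucleotide character '%s' at position %d in '%s'",
                 substr(seq_up, bad, bad), bad, chrom), call. = FALSE)
  }
  # split on N so no locus spans an ambiguous base
  seg_pos <- gregexpr("[ACGT]+", seq_up)[[1]]
  loci <- list()
  if (seg_pos[1] > 0L) {
    segs <- regmatches(seq_up, gregexpr("[ACGT]+", seq_up))[[1]]
    loci <- purrr::list_flatten(purrr::map2(
      segs, as.integer(seg_pos) - 1L,
      function(s, off) scan_segment(s, off, params$min_repeats)
    ))
    loci <- purrr::compact(loci)
  }
  if (length(loci) == 0L) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      motif = character(), canonical_motif = character(),
      unit_length = integer(), n_repeats = integer(), length_bp = integer(),
      length_class = character(), compound_id = character()
    ))
  }
  dplyr::bind_rows(loci) |>
    tibble::as_tibble() |>
    dplyr::mutate(
      chrom = chrom,
      canonical_motif = canonical_motif(.data$motif),
      length_bp = .data$end - .data$start + 1L,
      length_class = classify_length(.data$length_bp),
      compound_id = NA_character_
    ) |>
    dplyr::arrange(.data$start, .data$unit_length) |>
    dplyr::select("chrom", "start", "end", "motif", "canonical_motif",
                  "unit_length", "n_repeats", "length_bp", "length_class",
                  "compound_id")
}

#' Mine SSRs across a set of sequences
#'
#' @param sequences Named character vector of sequences (e.g. from
#'   [read_fasta()]).
#' @inheritParams find_ssrs
#' @return A tibble of loci across all sequences, in input record order.
#' @export
find_ssrs_all <- function(sequences, params = ssr_search_params()) {
  stopifnot(!is.null(names(sequences)))
  purrr::map2(sequences, names(sequences),
              function(s, id) find_ssrs(s, chrom = id, params = params)) |>
    dplyr::bind_rows()
}

#' Annotate compound SSRs
#'
#' Consecutive loci on one chromosome separated by at most `gap` intervening
#' bases are flagged as one compound SSR (transitively). Loci remain
#' individually counted in summaries; compound membership is an annotation.
#'
#' @param loci Locus tibble from [find_ssrs()].
#' @param gap Maximum intervening bases (default 100).
#' @return The input tibble with `compound_id` filled for compound members
#'   (`"<chrom>.c<k>"`), `NA` for solitary loci.
#' @export
annotate_compound <- function(loci, gap = 100L) {
  loci |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .data$unit_length, .by_group = TRUE) |>
    dplyr::mutate(
      .gap_prev = .data$start - dplyr::lag(cummax(.data$end)) - 1L,
      .new_grp = dplyr::coalesce(.data$.gap_prev > gap, TRUE),
      .grp = cumsum(.data$.new_grp)
    ) |>
    dplyr::group_by(.data$chrom, .data$.grp) |>
    dplyr::mutate(
      compound_id = if (dplyr::n() > 1L) {
        paste0(.data$chrom[1], ".c", .data$.grp[1])
      } else NA_character_
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".gap_prev", -".new_grp", -".grp")
}

#' Headline SSR summary statistics from aggregate tallies
#'
#' The derived quantities reported for a genome-wide SSR scan: per-megabase
#' abundance and density, coverage and mean locus length. Exposed separately
#' from [summarize_genome()] so published aggregate tallies can be checked
#' for internal consistency.
#'
#' @param total_ssrs Number of loci.
#' @param total_ssr_bp Summed length of perfect SSRs in bp.
#' @param examined_bp Total sequence length examined in bp.
#' @return One-row tibble: `examined_bp`, `total_ssrs`, `total_ssr_bp`,
#'   `coverage_pct` (0-100), `relative_abundance` (loci/Mb),
#'   `relative_density` (bp/Mb), `mean_ssr_length_bp`.
#' @export
ssr_summary_stats <- function(total_ssrs, total_ssr_bp, examined_bp) {
  if (examined_bp <= 0) stop("examined_bp must be > 0", call. = FALSE)
  mb <- examined_bp / 1e6
  tibble::tibble(
    examined_bp = examined_bp,
    total_ssrs = total_ssrs,
    total_ssr_bp = total_ssr_bp,
    coverage_pct = 100 * total_ssr_bp / examined_bp,
    relative_abundance = total_ssrs / mb,
    relative_density = total_ssr_bp / mb,
    mean_ssr_length_bp = if (total_ssrs > 0) total_ssr_bp / total_ssrs else 0
  )
}

#' Genome-wide SSR summary
#'
#' Aggregates a locus table into the standard genome-scan report: totals,
#' coverage, per-Mb abundance and density, and a per-unit-length breakdown.
#'
#' @param loci Locus tibble from [find_ssrs()] / [find_ssrs_all()].
#' @param examined_bp Total length of sequence examined, in bp.
#' @return An object of class `ssr_genome_summary`; [generics::glance()]
#'   returns the totals row, [generics::tidy()] the per-unit-length table.
#' @export
summarize_genome <- function(loci, examined_bp) {
  if (examined_bp <= 0) stop("examined_bp must be > 0", call. = FALSE)
  mb <- examined_bp / 1e6
  totals <- ssr_summary_stats(nrow(loci), sum(loci$length_bp), examined_bp)
  if (nrow(loci) == 0L) {
    per_unit <- tibble::tibble(
      unit_length = 1:6, count = 0L, total_length_bp = 0L,
      mean_repeats = 0, min_repeats = 0L, max_repeats = 0L,
      relative_abundance = 0, relative_density = 0, pct_of_total = 0
    )
    return(structure(list(totals = totals, per_unit = per_unit),
                     class = "ssr_genome_summary"))
  }
  per_unit <- loci |>
    dplyr::group_by(unit_length = factor(.data$unit_length, levels = 1:6)) |>
    dplyr::summarise(
      count = dplyr::n(),
      total_length_bp = sum(.data$length_bp),
      mean_repeats = mean(.data$n_repeats),
      min_repeats = min(.data$n_repeats),
      max_repeats = max(.data$n_repeats),
      .groups = "drop"
    ) |>
    tidyr::complete(unit_length, fill = list(
      count = 0L, total_length_bp = 0L,
      mean_repeats = 0, min_repeats = 0L, max_repeats = 0L
    )) |>
    dplyr::mutate(
      unit_length = as.integer(as.character(.data$unit_length)),
      relative_abundance = .data$count / mb,
      relative_density = .data$total_length_bp / mb,
      pct_of_total = if (nrow(loci) > 0) 100 * .data$count / nrow(loci) else 0
    )
  structure(list(totals = totals, per_unit = per_unit),
            class = "ssr_genome_summary")
}

#' @export
print.ssr_genome_summary <- function(x, ...) {
  cat("Genome SSR summary\n")
  t <- x$totals
  cat(sprintf("  examined: %s bp; %s SSRs covering %s bp (%.2f%%)\n",
              format(t$examined_bp, big.mark = ","),
              format(t$total_ssrs, big.mark = ","),
              format(t$total_ssr_bp, big.mark = ","), t$coverage_pct))
  cat(sprintf("  %.2f loci/Mb, %.2f bp/Mb, mean length %.2f bp\n",
              t$relative_abundance, t$relative_density, t$mean_ssr_length_bp))
  print(x$per_unit)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.ssr_genome_summary <- function(x, ...) x$per_unit

#' @importFrom generics glance
#' @export
glance.ssr_genome_summary <- function(x, ...) x$totals

#' SSR counts in fixed genomic windows
#'
#' Counts loci per non-overlapping window along each chromosome; window `i`
#' covers bases `(i-1)*w + 1 .. i*w` (last window truncated) and a locus is
#' assigned to the window containing its start.
#'
#' @param loci Locus tibble.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param window_bp Window size (default 100 kb).
#' @return Tibble: `chrom`, `window`, `window_start`, `window_end`, `n_ssrs`,
#'   with every window present (zero counts included).
#' @export
window_density <- function(loci, chrom_lengths, window_bp = 100000L) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0),
            window_bp >= 1)
  beyond <- loci$end > chrom_lengths[loci$chrom]
  if (any(beyond, na.rm = TRUE) || anyNA(beyond)) {
    i <- which(is.na(beyond) | beyond)[1]
    stop(sprintf("locus %s:%d-%d lies beyond the stated chromosome length",
                 loci$chrom[i], loci$start[i], loci$end[i]), call. = FALSE)
  }
  grid <- purrr::imap(chrom_lengths, function(len, ch) {
    nwin <- ceiling(len / window_bp)
    tibble::tibble(
      chrom = ch, window = seq_len(nwin),
      window_start = (seq_len(nwin) - 1L) * window_bp + 1,
      window_end = pmin(seq_len(nwin) * window_bp, len)
    )
  }) |> dplyr::bind_rows()
  counts <- loci |>
    dplyr::mutate(window = (.data$start - 1L) %/% window_bp + 1L) |>
    dplyr::count(.data$chrom, .data$window, name = "n_ssrs")
  grid |>
    dplyr::left_join(counts, by = c("chrom", "window")) |>
    dplyr::mutate(n_ssrs = dplyr::coalesce(.data$n_ssrs, 0L))
}
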