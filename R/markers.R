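#' GC content of a nucleotide sequence
#'
#' @param seq Character vector of nucleotide strings (A/C/G/T).
#' @return Numeric vector, percent G+C on the 0-100 scale.
#' @export
#' @examples
#' gc_content("ATGC")  # 50
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (any(!nzchar(seq))) stop("empty sequence", call. = FALSE)
  if (any(grepl("[^ACGT]", seq))) stop("sequences must be over A/C/G/T", call. = FALSE)
  100 * (stringr::str_count(seq, "[GC]")) / nchar(seq)
}

# Allawi & SantaLucia (1997) unified nearest-neighbour parameters.
# dH kcal/mol, dS cal/(mol K); duplex initiation split into terminal
# A/T vs G/C contributions.
nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

tm_nn_one <- function(s, na_mM, ct_nM) {
  n <- nchar(s)
  steps <- substring(s, seq_len(n - 1L), seq_len(n - 1L) + 1L)
  dh <- sum(nn_dh[steps])
  ds <- sum(nn_ds[steps])
  for (terminal in c(substr(s, 1L, 1L), substr(s, n, n))) {
    if (terminal %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  # entropy salt correction (SantaLucia 1998), monovalent cation in mol/L
  ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  r_gas <- 1.987
  dh * 1000 / (ds + r_gas * log(ct_nM * 1e-9 / 4)) - 273.15
}

#' Melting temperature of a primer
#'
#' Two estimators: the Wallace rule `2(A+T) + 4(G+C)` for quick hand checks,
#' and nearest-neighbour thermodynamics (Allawi & SantaLucia 1997 unified
#' parameters, entropy-based salt correction) assuming a non-self-complementary
#' duplex in excess of one strand.
#'
#' @param seq Character vector of primer sequences (A/C/G/T), length >= 8.
#' @param method `"nn"` (default) or `"wallace"`.
#' @param na_mM Monovalent cation concentration in mM (nn only, default 50).
#' @param ct_nM Total strand concentration in nM (nn only, default 250).
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
#' @examples
#' melting_temp("AAAATTTTGGGGCCCC", method = "wallace")  # 48
melting_temp <- function(seq, method = c("nn", "wallace"),
                         na_mM = 50, ct_nM = 250) {
  method <- match.arg(method)
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) stop("sequences must be over A/C/G/T", call. = FALSE)
  if (any(nchar(seq) < 8L)) stop("primers must be >= 8 nt", call. = FALSE)
  if (method == "wallace") {
    at <- stringr::str_count(seq, "[AT]")
    gc <- stringr::str_count(seq, "[GC]")
    return(2 * at + 4 * gc)
  }
  vapply(seq, tm_nn_one, numeric(1), na_mM = na_mM, ct_nM = ct_nM,
         USE.NAMES = FALSE)
}

#' Primer design acceptance criteria
#'
#' Windows within which a primer pair is accepted: primer length, GC content,
#' melting temperature, forward/reverse Tm difference, and PCR product size.
#' Defaults follow common fragment-analysis practice: 18-27 bp primers,
#' 40-60% GC, Tm 55-65 degrees C with less than 3 degrees between the two
#' primers, and products of 100-280 bp (sized on capillary electrophoresis).
#'
#' @param length_range,gc_range,tm_range,product_range Two-element numeric
#'   ranges (inclusive).
#' @param max_tm_diff Maximum absolute Tm difference (exclusive bound).
#' @return A list of class `design_criteria`.
#' @export
design_criteria <- function(length_range = c(18, 27), gc_range = c(40, 60),
                            tm_range = c(55, 65), max_tm_diff = 3,
                            product_range = c(100, 280)) {
  for (r in list(length_range, gc_range, tm_range, product_range)) {
    if (length(r) != 2L || r[1] > r[2]) stop("invalid range", call. = FALSE)
  }
  structure(list(length_range = length_range, gc_range = gc_range,
                 tm_range = tm_range, max_tm_diff = max_tm_diff,
                 product_range = product_range),
            class = "design_criteria")
}

m13_tail_seq <- "TGTAAAACGACGGCCAGT"

strip_m13 <- function(seq) {
  sub(paste0("^", m13_tail_seq), "", toupper(seq))
}

#' Check one primer pair against design criteria
#'
#' Returns the list of violated criteria (empty character vector means pass).
#' An M13 universal tail, if present at the 5' end, is stripped before any
#' computation: tails are synthesis metadata, not annealing sequence.
#'
#' @param forward,reverse Primer sequences 5'->3'.
#' @param product_size Expected product size in bp (`NA` to skip the check).
#' @param criteria A [design_criteria()] object.
#' @param tm_method Passed to [melting_temp()].
#' @return Character vector of reason codes among `"length"`, `"gc"`, `"tm"`,
#'   `"tm_diff"`, `"product_size"`.
#' @export
check_primer_pair <- function(forward, reverse, product_size = NA,
                              criteria = design_criteria(),
                              tm_method = "nn") {
  f <- strip_m13(forward); r <- strip_m13(reverse)
  reasons <- character()
  in_range <- function(x, rng) x >= rng[1] & x <= rng[2]
  if (!all(in_range(nchar(c(f, r)), criteria$length_range))) {
    reasons <- c(reasons, "length")
  }
  if (!all(in_range(gc_content(c(f, r)), criteria$gc_range))) {
    reasons <- c(reasons, "gc")
  }
  tms <- melting_temp(c(f, r), method = tm_method)
  if (!all(in_range(tms, criteria$tm_range))) reasons <- c(reasons, "tm")
  if (!(abs(diff(tms)) < criteria$max_tm_diff)) reasons <- c(reasons, "tm_diff")
  if (!is.na(product_size) &&
      !in_range(product_size, criteria$product_range)) {
    reasons <- c(reasons, "product_size")
  }
  reasons
}

#' Check a primer panel against design criteria
#'
#' Data-frame-first wrapper over [check_primer_pair()].
#'
#' @param panel Tibble with columns `name`, `forward`, `reverse` and
#'   optionally `product_size`.
#' @inheritParams check_primer_pair
#' @return The panel with added columns `pass` (logical) and `reasons`
#'   (list-column of reason codes).
#' @export
check_primers <- function(panel, criteria = design_criteria(),
                          tm_method = "nn") {
  stopifnot(all(c("name", "forward", "reverse") %in% names(panel)))
  if (anyDuplicated(panel$name)) stop("primer names must be unique", call. = FALSE)
  ps <- if ("product_size" %in% names(panel)) panel$product_size else NA
  panel |>
    dplyr::mutate(
      reasons = purrr::pmap(
        list(.data$forward, .data$reverse, rep_len(ps, dplyr::n())),
        function(f, r, p) check_primer_pair(f, r, p, criteria, tm_method)
      ),
      pass = purrr::map_lgl(.data$reasons, \(x) length(x) == 0L)
    )
}

# positions (1-based within the pattern) that must match the subject exactly
hits_with_seed <- function(subject, pattern, max_mismatch, seed_at_start) {
  m <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mismatch)
  st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
  keep <- st >= 1L & en <= length(subject)  # drop out-of-range fuzzy hits
  st <- st[keep]; en <- en[keep]
  if (max_mismatch > 0L && length(st)) {
    k <- nchar(pattern)
    seed <- if (seed_at_start) substr(pattern, 1L, 3L) else substr(pattern, k - 2L, k)
    ok <- vapply(seq_along(st), function(i) {
      rng <- if (seed_at_start) st[i]:(st[i] + 2L) else (en[i] - 2L):en[i]
      as.character(subject[rng[1]:rng[length(rng)]]) == seed
    }, logical(1))
    st <- st[ok]; en <- en[ok]
  }
  list(start = st, end = en)
}

#' Virtual (in-silico) PCR against a genome
#'
#' Predicts every amplicon a primer pair would produce: sites where the
#' forward primer matches one strand and the reverse primer matches the
#' opposite strand in convergent orientation, with non-overlapping binding
#' sites and a product no longer than `max_product`. Matching is exact by
#' default; when mismatches are allowed, the 3'-terminal 3 bases of each
#' primer must still match exactly.
#'
#' @param sequences Named character vector of genome sequences.
#' @param forward,reverse Primer sequences 5'->3' (>= 12 nt; M13 tails are
#'   stripped).
#' @param max_product Maximum product size in bp (default 5000).
#' @param max_mismatch Mismatches tolerated per primer (default 0).
#' @return Tibble of predictions: `chrom`, `start`, `end` (1-based inclusive
#'   outer span), `product_size`, `strand` (strand carrying the forward
#'   primer), deduplicated and sorted.
#' @export
insilico_pcr <- function(sequences, forward, reverse,
                         max_product = 5000L, max_mismatch = 0L) {
  forward <- strip_m13(forward); reverse <- strip_m13(reverse)
  if (nchar(forward) < 12L || nchar(reverse) < 12L) {
    stop("primers must be >= 12 nt for virtual PCR", call. = FALSE)
  }
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  res <- purrr::imap(sequences, function(s, ch) {
    subj <- Biostrings::DNAString(toupper(s))
    out <- list()
    # forward on plus strand; reverse site appears as revcomp(reverse) downstream
    f <- hits_with_seed(subj, forward, max_mismatch, seed_at_start = FALSE)
    r <- hits_with_seed(subj, rc(reverse), max_mismatch, seed_at_start = TRUE)
    if (length(f$start) && length(r$start)) {
      g <- expand.grid(fi = seq_along(f$start), ri = seq_along(r$start))
      fs <- f$start[g$fi]; fe <- f$end[g$fi]
      rs <- r$start[g$ri]; re <- r$end[g$ri]
      ok <- rs > fe & (re - fs + 1L) <= max_product
      if (any(ok)) {
        out$plus <- tibble::tibble(chrom = ch, start = fs[ok], end = re[ok],
                                   strand = "+")
      }
    }
    # forward on minus strand: its site is revcomp(forward) at the right end,
    # the reverse primer matches the plus strand at the left end
    f2 <- hits_with_seed(subj, rc(forward), max_mismatch, seed_at_start = TRUE)
    r2 <- hits_with_seed(subj, reverse, max_mismatch, seed_at_start = FALSE)
    if (length(f2$start) && length(r2$start)) {
      g <- expand.grid(fi = seq_along(f2$start), ri = seq_along(r2$start))
      fs <- f2$start[g$fi]; fe <- f2$end[g$fi]
      rs <- r2$start[g$ri]; re <- r2$end[g$ri]
      ok <- fs > re & (fe - rs + 1L) <= max_product
      if (any(ok)) {
        out$minus <- tibble::tibble(chrom = ch, start = rs[ok], end = fe[ok],
                                    strand = "-")
      }
    }
    dplyr::bind_rows(out)
  })
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), product_size = integer(),
                          strand = character()))
  }
  res |>
    dplyr::mutate(product_size = .data$end - .data$start + 1L) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$strand,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::select("chrom", "start", "end", "product_size", "strand")
}

#' Run virtual PCR for a whole primer panel
#'
#' @param sequences Named character vector of genome sequences.
#' @param panel Tibble with `name`, `forward`, `reverse`.
#' @inheritParams insilico_pcr
#' @return Tibble of predictions with a leading `primer` column.
#' @export
insilico_pcr_panel <- function(sequences, panel, max_product = 5000L,
                               max_mismatch = 0L) {
  purrr::pmap(panel[c("name", "forward", "reverse")],
              function(name, forward, reverse) {
                insilico_pcr(sequences, forward, reverse,
                             max_product, max_mismatch) |>
                  dplyr::mutate(primer = name, .before = 1)
              }) |>
    dplyr::bind_rows()
}

#' Classify a marker from its virtual-amplification hits
#'
#' One genomic amplification site makes a marker locus-specific
#' ("monomorphic" in the in-silico screening sense), several sites make it
#' multi-locus ("polymorphic"); no site means the primers find no template.
#'
#' @param predictions Tibble of [insilico_pcr()] hits for one primer pair,
#'   or an integer hit count.
#' @return `"null"`, `"monomorphic"` or `"polymorphic"`.
#' @export
classify_marker <- function(predictions) {
  n <- if (is.data.frame(predictions)) nrow(predictions) else as.integer(predictions)
  if (n == 0L) "null" else if (n == 1L) "monomorphic" else "polymorphic"
}
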