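#' Read a FASTA file
#'
#' Multi-record, line-wrapped FASTA; CRLF endings and lowercase bases are
#' tolerated. Record order is preserved and ids are the first whitespace
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(gsub("\r", "", as.character(x)))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a genotype table from CSV
#'
#' Long-format CSV with header `sample_id, locus, a1, a2, a3, a4`; blank
#' cells are missing, sizes must be positive integers, and a later allele
#' column may not be filled before an earlier one. Sample and locus order
#' follow first appearance.
#'
#' @param path Path to the CSV.
#' @return A genotype table tibble (see [as_genotype_table()]).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), locus = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  as_genotype_table(x)
}

#' Write a genotype table to CSV
#' @param tbl Genotype table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(tbl, path) {
  readr::write_csv(as_genotype_table(tbl), path, na = "")
  invisible(path)
}

#' Read a coordinate table from CSV
#'
#' Expects columns `sample_id`, `lat`, `lon` in decimal degrees.
#' @param path Path to the CSV.
#' @return Tibble `sample_id`, `lat`, `lon`.
#' @export
read_coords <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    lat = readr::col_double(), lon = readr::col_double()
  ), progress = FALSE)
  if (any(abs(x$lat) > 90) || any(abs(x$lon) > 180)) {
    stop("coordinates out of range in ", path, call. = FALSE)
  }
  x
}

#' Read an LnP(K) replicate table from CSV
#'
#' Columns `K`, `replicate`, `lnp`; importable from external structure runs.
#' @param path Path to the CSV.
#' @return Tibble suitable for [evanno()].
#' @export
read_lnp <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    K = readr::col_integer(), replicate = readr::col_integer(),
    lnp = readr::col_double()
  ), progress = FALSE)
}

#' Write a labelled square matrix as TSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a labelled square matrix from TSV
#' @param path Path written by [write_matrix()].
#' @return Matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$id
  m
}

#' Write a tree in Newick format
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export SSR loci as BED6
#'
#' Native locus coordinates are 1-based inclusive; BED is 0-based
#' half-open, so `start` is decremented and `end` kept.
#'
#' @param loci Locus tibble from [find_ssrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  bed <- tibble::tibble(
    chrom = loci$chrom,
    start = loci$start - 1L,
    end = loci$end,
    name = paste0("(", loci$motif, ")", loci$n_repeats),
    score = 0L,
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write an SSR locus table as TSV
#' @param loci Locus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_table <- function(loci, path) {
  readr::write_tsv(loci, path)
  invisible(path)
}

#' Read an SSR locus table written by [write_ssr_table()]
#' @param path Path to the TSV.
#' @return Locus tibble.
#' @export
read_ssr_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), motif = readr::col_character(),
    canonical_motif = readr::col_character(),
    unit_length = readr::col_integer(), n_repeats = readr::col_integer(),
    length_bp = readr::col_integer(), length_class = readr::col_character(),
    compound_id = readr::col_character()
  ), progress = FALSE)
}
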