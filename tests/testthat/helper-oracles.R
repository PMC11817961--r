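# Independent brute-force oracles and small fixture builders.
# These deliberately use different mechanics from the package implementation.

random_dna <- function(n, seed, gc = 0.5, n_rate = 0) {
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sample(names(probs), n, replace = TRUE, prob = probs)
  if (n_rate > 0) s[runif(n) < n_rate] <- "N"
  paste(s, collapse = "")
}

oracle_primitive <- function(unit) {
  k <- nchar(unit)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 && grepl(paste0("^(.{", d, "})\\1+$"), unit)) return(FALSE)
  }
  TRUE
}

# exhaustive scanner: tests every (position, unit_length) pair
oracle_find_ssrs <- function(s, min_repeats = c(10, 6, 5, 5, 5, 5)) {
  s <- toupper(s)
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  rows <- list()
  for (k in 1:6) {
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      unit <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", unit)) next
      # must be the start of a maximal period-k region
      if (i > 1 && ch[i - 1] == ch[i - 1 + k]) next
      m <- 1
      while (i + (m + 1) * k - 1 <= n &&
             substr(s, i + m * k, i + (m + 1) * k - 1) == unit) {
        m <- m + 1
      }
      if (m >= min_repeats[k] && oracle_primitive(unit)) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i, end = i + m * k - 1, motif = unit,
          unit_length = k, n_repeats = m
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit_length = integer(), n_repeats = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_length), , drop = FALSE]
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# naive all-positions scanner for virtual PCR (exact matching only)
oracle_epcr <- function(seqs, fwd, rev, max_product = 5000) {
  rows <- list()
  match_positions <- function(s, pat) {
    n <- nchar(s); k <- nchar(pat)
    if (n < k) return(integer())
    which(vapply(seq_len(n - k + 1),
                 function(i) substr(s, i, i + k - 1) == pat, logical(1)))
  }
  for (ch in names(seqs)) {
    s <- toupper(seqs[[ch]])
    fs <- match_positions(s, fwd)
    rs <- match_positions(s, oracle_revcomp(rev))
    for (f in fs) for (r in rs) {
      fe <- f + nchar(fwd) - 1
      re <- r + nchar(rev) - 1
      if (r > fe && re - f + 1 <= max_product) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start = f, end = re,
          product_size = re - f + 1, strand = "+")
      }
    }
    f2 <- match_positions(s, oracle_revcomp(fwd))
    r2 <- match_positions(s, rev)
    for (f in f2) for (r in r2) {
      fe <- f + nchar(fwd) - 1
      re <- r + nchar(rev) - 1
      if (f > re && fe - r + 1 <= max_product) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start = r, end = fe,
          product_size = fe - r + 1, strand = "-")
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      product_size = integer(), strand = character()))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# PIC via the explicit double sum 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2
oracle_pic <- function(p) {
  s <- 1 - sum(p^2)
  for (i in seq_along(p)) {
    j <- seq_along(p)
    j <- j[j > i]
    if (length(j)) s <- s - sum(2 * p[i]^2 * p[j]^2)
  }
  s
}

# PI by enumerating unordered HWE genotypes: sum over g of P(g)^2
oracle_pi <- function(p) {
  total <- 0
  for (i in seq_along(p)) for (j in i:length(p)) {
    pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    total <- total + pg^2
  }
  total
}

# simple builder: genotype table from a matrix of "a/b" strings (NA missing)
geno_from_strings <- function(m) {
  ids <- rownames(m); loci <- colnames(m)
  rows <- list()
  for (i in seq_along(ids)) for (l in seq_along(loci)) {
    g <- m[i, l]
    if (is.na(g)) {
      a <- c(NA_integer_, NA_integer_)
    } else {
      a <- as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
      if (length(a) == 1) a <- c(a, NA_integer_)
      if (length(a) == 2 && !is.na(a[2]) && a[1] == a[2]) a[2] <- NA_integer_
    }
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = ids[i], locus = loci[l], a1 = a[1], a2 = a[2],
      a3 = NA_integer_, a4 = NA_integer_)
  }
  do.call(rbind, rows)
}
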