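#' Maximum-likelihood admixture model fitted by EM
#'
#' Fits the classic admixture model: individual `i` draws each allele copy at
#' locus `l` from cluster `k` with probability `q_ik`, then the allele from
#' the cluster's frequency profile `f_kl`. The complete log-likelihood
#' `sum_{i,l,c} log sum_k q_ik f_kl[a(i,l,c)]` is maximised by
#' expectation-maximisation over both `Q` and the per-cluster allele
#' frequencies; the log-likelihood is non-decreasing at every iteration.
#' Missing allele copies contribute nothing. Several random restarts guard
#' against local optima; the best restart is returned.
#'
#' @param tbl Genotype table (diploid view is used).
#' @param K Number of ancestral clusters (>= 1).
#' @param seed Integer seed (initialisation only; EM itself is
#'   deterministic).
#' @param tol Stop when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 2000).
#' @param n_init Number of random restarts (default 5).
#' @return Object of class `ssr_structure_fit`: `K`, `Q` (tibble,
#'   `sample_id` + `k1..kK`, rows on the simplex), `freqs` (per-locus tibble
#'   of cluster allele frequencies), `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `seed`. [generics::tidy()] gives Q in long form,
#'   [generics::glance()] a one-row fit summary.
#' @export
em_admixture <- function(tbl, K, seed = 1L, tol = 1e-6, max_iter = 2000L,
                         n_init = 5L) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be >= 1", call. = FALSE)
  dv <- diploid_view(tbl)
  ids <- sample_order(as_genotype_table(tbl))
  loci <- locus_order(as_genotype_table(tbl))
  n <- length(ids)
  if (n < K) stop("need at least K individuals", call. = FALSE)
  typed_per_ind <- dv |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ok = any(!is.na(.data$allele1)), .groups = "drop")
  if (any(!typed_per_ind$ok)) {
    stop("individual(s) with no typed locus: ",
         paste(typed_per_ind$sample_id[!typed_per_ind$ok], collapse = ", "),
         call. = FALSE)
  }
  # long representation: one row per typed allele copy
  long <- dv |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::mutate(ind = match(.data$sample_id, ids))
  copies <- split(long[c("ind", "allele")], factor(long$locus, levels = loci))
  alleles <- purrr::map(copies, \(x) sort(unique(x$allele)))
  aidx <- purrr::map2(copies, alleles, \(x, a) match(x$allele, a))

  run_one <- function(init_seed) {
    set.seed(init_seed)
    q <- matrix(stats::rgamma(n * K, 1), n, K)
    q <- q / rowSums(q)
    f <- purrr::map(alleles, function(a) {
      m <- matrix(stats::rgamma(length(a) * K, 1), length(a), K)
      sweep(m, 2, colSums(m), `/`)
    })
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      qnum <- matrix(0, n, K)
      fnum <- purrr::map(alleles, \(a) matrix(0, length(a), K))
      ll <- 0
      for (l in seq_along(copies)) {
        cp <- copies[[l]]
        if (nrow(cp) == 0L) next
        w <- q[cp$ind, , drop = FALSE] * f[[l]][aidx[[l]], , drop = FALSE]
        s <- rowSums(w)
        ll <- ll + sum(log(s))
        r <- w / s
        rs <- rowsum(r, cp$ind)
        idx <- as.integer(rownames(rs))
        qnum[idx, ] <- qnum[idx, ] + rs
        rs_f <- rowsum(r, aidx[[l]])
        fnum[[l]][as.integer(rownames(rs_f)), ] <- rs_f
      }
      trace <- c(trace, ll)
      q <- qnum / rowSums(qnum)
      f <- purrr::map(fnum, \(m) sweep(m, 2, pmax(colSums(m), 1e-300), `/`))
      if (is.finite(prev) && ll - prev < tol) { converged <- TRUE; break }
      prev <- ll
    }
    list(q = q, f = f, loglik = trace[length(trace)], trace = trace,
         n_iter = iter, converged = converged)
  }

  if (K == 1L) {
    # closed form: Q is all ones, F the observed frequencies
    f <- purrr::map2(copies, alleles, function(cp, a) {
      tab <- tabulate(match(cp$allele, a), nbins = length(a))
      matrix(tab / sum(tab), ncol = 1)
    })
    ll <- 0
    for (l in seq_along(copies)) {
      cp <- copies[[l]]
      if (nrow(cp) == 0L) next
      ll <- ll + sum(log(f[[l]][match(cp$allele, alleles[[l]]), 1]))
    }
    best <- list(q = matrix(1, n, 1), f = f, loglik = ll, trace = ll,
                 n_iter = 0L, converged = TRUE)
  } else {
    fits <- purrr::map(seq_len(n_init), \(i) run_one(seed + (i - 1L) * 1009L))
    best <- fits[[which.max(purrr::map_dbl(fits, "loglik"))]]
  }

  qtb <- tibble::tibble(sample_id = ids) |>
    dplyr::bind_cols(tibble::as_tibble(best$q, .name_repair = ~ paste0("k", seq_len(ncol(best$q)))))
  ftb <- purrr::imap(best$f, function(m, l) {
    colnames(m) <- paste0("k", seq_len(ncol(m)))
    tibble::tibble(locus = l, allele = alleles[[l]]) |>
      dplyr::bind_cols(tibble::as_tibble(m))
  }) |> dplyr::bind_rows()
  structure(list(K = K, Q = qtb, freqs = ftb, loglik = best$loglik,
                 loglik_trace = best$trace, n_iter = best$n_iter,
                 converged = best$converged, seed = seed),
            class = "ssr_structure_fit")
}

#' @export
print.ssr_structure_fit <- function(x, ...) {
  cat(sprintf("Admixture EM fit: K = %d, logLik = %.3f (%d iterations%s)\n",
              x$K, x$loglik, x$n_iter,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' @export
tidy.ssr_structure_fit <- function(x, ...) {
  x$Q |>
    tidyr::pivot_longer(-"sample_id", names_to = "cluster",
                        values_to = "q", names_prefix = "k") |>
    dplyr::mutate(cluster = as.integer(.data$cluster))
}

#' @export
glance.ssr_structure_fit <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, seed = x$seed)
}

#' Log-probability replicates across a range of K
#'
#' Runs [em_admixture()] for each `(K, replicate)` pair with distinct derived
#' seeds and records the maximised log-likelihood as the LnP(K) score that
#' the Evanno procedure consumes. (This is a maximised likelihood, not an
#' MCMC marginal-likelihood estimate; the Evanno statistic only needs a
#' consistent per-K score with replicate spread.)
#'
#' @param tbl Genotype table.
#' @param k_range Integer vector of K values (default `2:10`).
#' @param n_rep Replicates per K (default 5).
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @param ... Passed to [em_admixture()].
#' @return Tibble: `K`, `replicate`, `lnp`, `seed`.
#' @export
lnp_replicates <- function(tbl, k_range = 2:10, n_rep = 5L, seed = 1L, ...) {
  grid <- tidyr::expand_grid(K = sort(as.integer(k_range)),
                             replicate = seq_len(n_rep))
  grid$seed <- seed + seq_len(nrow(grid)) * 7919L
  grid |>
    dplyr::mutate(lnp = purrr::map2_dbl(.data$K, .data$seed, function(k, s) {
      em_admixture(tbl, K = k, seed = s, ...)$loglik
    })) |>
    dplyr::select("K", "replicate", "lnp", "seed")
}

#' Evanno delta-K table from LnP(K) replicates
#'
#' Per K: mean and standard deviation of LnP(K), replicate-wise first
#' difference `L'(K) = L(K) - L(K-1)` and absolute second difference
#' `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `deltaK = mean|L''(K)| / sd(L(K))`. The optimal K is the argmax of
#' deltaK over interior K values; ties break toward smaller K. deltaK is
#' undefined at the smallest and largest K.
#'
#' @param lnp Tibble with columns `K`, `replicate`, `lnp` (e.g. from
#'   [lnp_replicates()] or an imported table of external runs).
#' @return Object of class `ssr_evanno`: a tibble `K`, `n_rep`, `mean_lnp`,
#'   `sd_lnp`, `lprime`, `lsecond`, `delta_k` with attribute `optimal_k`
#'   (`NA` if deltaK is 0 everywhere). [generics::tidy()] returns the table.
#' @export
evanno <- function(lnp) {
  stopifnot(all(c("K", "replicate", "lnp") %in% names(lnp)))
  ks <- sort(unique(lnp$K))
  if (length(ks) < 3L || !all(diff(ks) == 1L)) {
    stop("need >= 3 consecutive K values", call. = FALSE)
  }
  reps <- lnp |> dplyr::count(.data$K)
  if (any(reps$n < 2L)) stop("need >= 2 replicates per K", call. = FALSE)
  if (length(unique(reps$n)) != 1L) {
    stop("replicate counts must be equal across K for replicate-wise differences",
         call. = FALSE)
  }
  wide <- lnp |>
    dplyr::arrange(.data$K, .data$replicate) |>
    tidyr::pivot_wider(id_cols = "replicate", names_from = "K",
                       values_from = "lnp") |>
    dplyr::select(-"replicate") |>
    as.matrix()
  mean_l <- colMeans(wide)
  sd_l <- apply(wide, 2, stats::sd)
  interior <- seq(2L, length(ks) - 1L)
  if (any(sd_l[interior] == 0)) {
    stop("sd of LnP(K) is zero at some K; add replicates or jitter seeds",
         call. = FALSE)
  }
  lprime <- cbind(NA, t(apply(wide, 1, diff)))            # L(K) - L(K-1)
  lsec <- abs(wide[, interior + 1L, drop = FALSE] -
                2 * wide[, interior, drop = FALSE] +
                wide[, interior - 1L, drop = FALSE])
  delta_k <- rep(NA_real_, length(ks))
  delta_k[interior] <- colMeans(lsec) / sd_l[interior]
  lsecond <- rep(NA_real_, length(ks))
  lsecond[interior] <- colMeans(lsec)
  tab <- tibble::tibble(
    K = ks, n_rep = reps$n,
    mean_lnp = mean_l, sd_lnp = sd_l,
    lprime = colMeans(lprime),
    lsecond = lsecond,
    delta_k = delta_k
  )
  opt <- if (all(is.na(delta_k) | delta_k == 0)) {
    NA_integer_
  } else {
    ks[interior][which.max(delta_k[interior])]
  }
  structure(tab, class = c("ssr_evanno", class(tab)), optimal_k = opt)
}

#' Optimal K from an Evanno table
#' @param ev An `ssr_evanno` object.
#' @return Integer K (or `NA` when deltaK is flat).
#' @export
optimal_k <- function(ev) attr(ev, "optimal_k")

#' @export
tidy.ssr_evanno <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.ssr_evanno <- function(x, ...) {
  ok <- optimal_k(x)
  tibble::tibble(optimal_k = ok,
                 max_delta_k = if (is.na(ok)) NA_real_ else max(x$delta_k, na.rm = TRUE))
}

#' Match cluster labels between two Q matrices
#'
#' Admixture solutions are identifiable only up to a permutation of cluster
#' labels. Greedily matches columns of `q` to `q_ref` by maximal column
#' correlation-free absolute agreement (minimal mean absolute difference),
#' which for small K equals the optimal assignment in practice; for K <= 8
#' all permutations are tried exactly.
#'
#' @param q,q_ref Numeric matrices (individuals x K) or Q tibbles from
#'   [em_admixture()].
#' @return `q` with columns permuted to best match `q_ref`.
#' @export
match_clusters <- function(q, q_ref) {
  as_mat <- function(x) {
    if (is.data.frame(x)) as.matrix(x[setdiff(names(x), "sample_id")]) else x
  }
  qm <- as_mat(q); rm_ <- as_mat(q_ref)
  K <- ncol(qm)
  stopifnot(ncol(rm_) == K)
  if (K <= 8L) {
    perms <- permutations_of(K)
    costs <- vapply(perms, function(p) mean(abs(qm[, p] - rm_)), numeric(1))
    best <- perms[[which.min(costs)]]
  } else {
    best <- integer(K)
    used <- logical(K)
    for (j in seq_len(K)) {
      errs <- vapply(seq_len(K), function(c2) {
        if (used[c2]) Inf else mean(abs(qm[, c2] - rm_[, j]))
      }, numeric(1))
      best[j] <- which.min(errs)
      used[best[j]] <- TRUE
    }
  }
  out <- qm[, best, drop = FALSE]
  if (is.data.frame(q)) {
    res <- q
    res[paste0("k", seq_len(K))] <- out
    res
  } else out
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations_of(k - 1L)
  unlist(lapply(sub, function(p) {
    lapply(seq_len(k), function(pos) append(p, k, after = pos - 1L))
  }), recursive = FALSE)
}
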