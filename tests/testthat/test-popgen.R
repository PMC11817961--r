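two_allele_table <- function() {
  # 10 individuals, all heterozygous 180/184 at one locus
  tibble::tibble(sample_id = sprintf("s%02d", 1:10), locus = "L1",
                 a1 = 180L, a2 = 184L, a3 = NA_integer_, a4 = NA_integer_)
}

test_that("allele frequencies tally two copies per non-missing individual", {
  af <- allele_freqs(two_allele_table())
  expect_equal(af$freq, c(0.5, 0.5))
  g <- geno_from_strings(matrix(c("180/180", "180/180", "180/180", "180/180",
                                  "184/184"), ncol = 1,
                                dimnames = list(paste0("s", 1:5), "L1")))
  af2 <- allele_freqs(g)
  expect_equal(af2$freq[af2$allele == 180], 0.8)
  expect_equal(af2$freq[af2$allele == 184], 0.2)
  # a single recorded size is a homozygote (two copies)
  g3 <- g; g3$a2 <- NA_integer_
  expect_equal(allele_freqs(g3)$freq, af2$freq)
  # all-missing locus errors with the locus name
  g4 <- two_allele_table(); g4$a1 <- NA_integer_; g4$a2 <- NA_integer_
  expect_error(allele_freqs(g4), "L1")
})

test_that("frequencies equal a brute-force tally on random tables", {
  set.seed(91)
  sizes <- seq(100, 140, by = 2)
  m <- matrix(paste0(sample(sizes, 60, TRUE), "/", sample(sizes, 60, TRUE)),
              nrow = 20, dimnames = list(paste0("s", 1:20), paste0("L", 1:3)))
  g <- geno_from_strings(m)
  af <- allele_freqs(g)
  for (l in paste0("L", 1:3)) {
    copies <- unlist(strsplit(m[, l], "/"))
    tal <- table(copies) / length(copies)
    got <- af[af$locus == l, ]
    expect_equal(got$freq, as.numeric(tal[as.character(got$allele)]))
  }
})

test_that("diversity statistics match closed forms", {
  d <- ssr_diversity(two_allele_table())
  expect_equal(d$na, 2L)
  expect_equal(d$ne, 2)
  expect_equal(d$he, 0.5)
  expect_equal(d$ho, 1)
  expect_equal(d$shannon, log(2))
  expect_equal(d$pic, 0.375)
  # single allele
  g1 <- geno_from_strings(matrix(rep("100/100", 4), ncol = 1,
                                 dimnames = list(paste0("s", 1:4), "L1")))
  d1 <- ssr_diversity(g1)
  expect_equal(unlist(d1[c("na", "ne", "ho", "he", "shannon", "pic")]),
               c(na = 1, ne = 1, ho = 0, he = 0, shannon = 0, pic = 0))
  # four equifrequent alleles
  m4 <- matrix(c("100/102", "104/106", "100/104", "102/106"), ncol = 1,
               dimnames = list(paste0("s", 1:4), "L1"))
  d4 <- ssr_diversity(geno_from_strings(m4))
  expect_equal(d4$ne, 4)
  expect_equal(d4$he, 0.75)
  expect_equal(d4$shannon, log(4))
})

test_that("PIC equals the explicit double-sum oracle on random frequencies", {
  set.seed(17)
  for (i in 1:20) {
    k <- sample(2:12, 1)
    p <- as.numeric(rmultinom(1, 500, rgamma(k, 1)))
    p <- p[p > 0] / sum(p)
    pic <- 1 - sum(p^2) - sum(p^2)^2 + sum(p^4)
    expect_equal(pic, oracle_pic(p), tolerance = 1e-12)
  }
})

test_that("diversity invariants hold on simulated panels", {
  pan <- simulate_panel(n = 60, n_loci = 8, K = 2, seed = 3)
  d <- ssr_diversity(pan$genotypes)
  expect_true(all(d$pic <= d$he + 1e-12))
  expect_true(all(d$he <= 1 - 1 / d$na + 1e-12))
  expect_true(all(d$ne <= d$na + 1e-12))
  expect_true(all(d$ne >= 1))
  expect_true(all(d$he >= 0 & d$he <= 1))
  expect_true(all((d$he == 0) == (d$na == 1)))
})

test_that("diversity estimates converge to generating values at large n", {
  # one cluster, known frequency profile: He-hat within 0.01 of 1 - sum p^2
  pan <- simulate_panel(n = 2000, n_loci = 5, K = 1, missing_rate = 0,
                        ibd = FALSE, seed = 11)
  d <- ssr_diversity(pan$genotypes)
  f <- pan$freqs_true
  for (l in unique(f$locus)) {
    he_true <- 1 - sum(f$k1[f$locus == l]^2)
    expect_lt(abs(d$he[d$locus == l] - he_true), 0.01)
  }
})

test_that("identity statistics match closed forms and the enumeration oracle", {
  ident <- ssr_identity(two_allele_table())
  expect_equal(ident$pi, 0.375)
  expect_equal(ident$pi_sibs, 0.59375)
  # single allele -> PI = PIsibs = 1
  g1 <- geno_from_strings(matrix(rep("100/100", 4), ncol = 1,
                                 dimnames = list(paste0("s", 1:4), "L1")))
  i1 <- ssr_identity(g1)
  expect_equal(i1$pi, 1)
  expect_equal(i1$pi_sibs, 1)
  # random frequencies: PI equals sum over genotypes of P(g)^2
  set.seed(23)
  for (i in 1:10) {
    k <- sample(2:8, 1)
    p <- as.numeric(rmultinom(1, 300, rgamma(k, 1)))
    p <- p[p > 0] / sum(p)
    pi_closed <- 2 * sum(p^2)^2 - sum(p^4)
    expect_equal(pi_closed, oracle_pi(p), tolerance = 1e-12)
  }
})

test_that("cumulative PI is non-increasing and ordered by informativeness", {
  pan <- simulate_panel(n = 80, n_loci = 10, K = 2, seed = 7)
  ident <- ssr_identity(pan$genotypes)
  expect_true(all(diff(ident$cum_pi) <= 1e-15))
  expect_true(all(diff(ident$pi) >= -1e-15))  # ascending PI order
  expect_true(all(ident$pi <= ident$pi_sibs))
  expect_true(all(ident$pi_sibs <= 1))
})

test_that("multilocus matches find exactly the planted duplicates", {
  pan <- simulate_panel(n = 40, n_loci = 10, K = 2, missing_rate = 0.05,
                        seed = 13)
  g <- pan$genotypes
  expect_equal(nrow(multilocus_match(g)), 0L)
  # duplicate one individual under a new id
  dup <- dplyr::mutate(g[g$sample_id == "S001", ], sample_id = "S999")
  g2 <- dplyr::bind_rows(g, dup)
  mm <- multilocus_match(g2)
  expect_equal(nrow(mm), 1L)
  expect_setequal(c(mm$sample_1, mm$sample_2), c("S001", "S999"))
})

test_that("similarity matrices are symmetric with unit diagonal and correct on constructions", {
  # identical individuals -> GS 1
  g <- geno_from_strings(matrix(c("100/102", "100/102", "104/106"), ncol = 1,
                                dimnames = list(c("a", "b", "c"), "L1")))
  gs <- gs_matrix(g)
  expect_equal(gs["a", "b"], 1)
  expect_true(isSymmetric(gs))
  expect_equal(diag(gs), c(a = 1, b = 1, c = 1))
  # disjoint single-band profiles over exactly two bands -> simple matching 0
  g2 <- geno_from_strings(matrix(c("100/100", "102/102"), ncol = 1,
                                 dimnames = list(c("a", "b"), "L1")))
  expect_equal(gs_matrix(g2, "simple_matching")["a", "b"], 0)
  expect_equal(gs_matrix(g2, "dice")["a", "b"], 0)
})

test_that("similarity equals a brute-force band comparison on random tables", {
  pan <- simulate_panel(n = 15, n_loci = 5, K = 2, missing_rate = 0.1, seed = 29)
  g <- pan$genotypes
  gs <- gs_matrix(g, "simple_matching")
  dv <- diploid_view(g)
  ids <- unique(g$sample_id)
  # brute force: enumerate every locus-allele band explicitly
  af <- allele_freqs(g)
  bands <- paste(af$locus, af$allele)
  prof <- function(id) {
    x <- dv[dv$sample_id == id & !is.na(dv$allele1), ]
    present <- unique(c(paste(x$locus, x$allele1), paste(x$locus, x$allele2)))
    typed_loci <- x$locus
    list(present = present, typed = typed_loci)
  }
  for (pair in list(c(1, 2), c(3, 9), c(5, 15))) {
    p1 <- prof(ids[pair[1]]); p2 <- prof(ids[pair[2]])
    shared_loci <- intersect(p1$typed, p2$typed)
    use <- bands[af$locus %in% shared_loci]
    a <- sum(use %in% p1$present & use %in% p2$present)
    d <- sum(!(use %in% p1$present) & !(use %in% p2$present))
    expect_equal(gs[ids[pair[1]], ids[pair[2]]], (a + d) / length(use))
  }
})

test_that("geographic distances are haversine on a 6371-km sphere", {
  co <- tibble::tibble(sample_id = c("a", "b", "c"),
                       lat = c(0, 0, 40.57), lon = c(0, 180, 111.93))
  d <- geo_distance(co)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], pi * 6371, tolerance = 1e-6)
  # spherical law of cosines as the independent check
  slc <- function(lat1, lon1, lat2, lon2) {
    r <- pi / 180
    6371 * acos(pmin(1, sin(lat1 * r) * sin(lat2 * r) +
                       cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)))
  }
  expect_equal(d["a", "c"], slc(0, 0, 40.57, 111.93), tolerance = 1e-6)
  expect_error(geo_distance(dplyr::mutate(co, lat = c(0, 95, 0))), "range")
})

test_that("mantel test recovers perfect correlation and is seed-stable", {
  set.seed(5)
  x <- matrix(rnorm(20), 10)
  d <- as.matrix(dist(x)); dimnames(d) <- list(letters[1:10], letters[1:10])
  m <- mantel_test(d, d, n_perm = 99, seed = 2)
  expect_equal(m$r, 1)
  m2 <- mantel_test(d, d, n_perm = 99, seed = 2)
  expect_equal(glance(m), glance(m2))
  expect_equal(m$p, 1 / 100, tolerance = 0.2)  # near the resolution floor
  d2 <- d[c(2:10, 1), c(2:10, 1)]
  expect_error(mantel_test(d, d2), "order")
})

test_that("mantel r matches vegan and the null p-values are calibrated", {
  skip_if_not_installed("vegan")
  set.seed(6)
  d1 <- as.matrix(dist(matrix(rnorm(30), 15)))
  d2 <- as.matrix(dist(matrix(rnorm(30), 15)))
  m <- mantel_test(d1, d2, n_perm = 999, seed = 3)
  v <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(m$r, unname(v$statistic), tolerance = 1e-12)
  # null calibration: p roughly uniform, mean r near 0
  ps <- rs <- numeric(60)
  for (i in 1:60) {
    a <- as.matrix(dist(matrix(rnorm(16, ), 8)))
    b <- as.matrix(dist(matrix(rnorm(16), 8)))
    mt <- mantel_test(a, b, n_perm = 199, seed = i)
    ps[i] <- mt$p; rs[i] <- mt$r
  }
  expect_lt(abs(mean(ps) - 0.5), 0.15)
  expect_lt(abs(mean(rs)), 0.12)
})

test_that("PCoA recovers closed-form and planted configurations", {
  # two points at distance d -> one axis at +/- d/2
  d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- pcoa_dist(d)
  expect_equal(sort(p$scores$axis1), c(-2, 2))
  expect_equal(p$pct_var, 100)
  # planted 2-D configuration recovered up to rotation/reflection
  set.seed(8)
  xy <- matrix(rnorm(40), 20)
  rownames(xy) <- paste0("s", 1:20)
  dm <- as.matrix(dist(xy))
  p2 <- pcoa_dist(dm)
  sc <- as.matrix(p2$scores[, c("axis1", "axis2")])
  # Procrustes via SVD of the cross-product
  a <- scale(xy, scale = FALSE); b <- scale(sc, scale = FALSE)
  sv <- svd(crossprod(b, a))
  rot <- sv$u %*% t(sv$v)
  expect_lt(max(abs(b %*% rot - a)), 1e-8)
  expect_equal(sum(p2$pct_var), 100)
  expect_error(pcoa_dist(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA agrees with an independent implementation", {
  pan <- simulate_panel(n = 30, n_loci = 8, K = 3, seed = 10)
  d <- genetic_dist(gs_matrix(pan$genotypes))
  p <- pcoa_dist(d)
  ref <- ape::pcoa(as.dist(d))
  k <- min(3, ncol(ref$vectors), ncol(p$scores) - 1)
  for (ax in seq_len(k)) {
    expect_equal(abs(as.numeric(p$scores[[paste0("axis", ax)]])),
                 abs(as.numeric(ref$vectors[, ax])), tolerance = 1e-6)
  }
})

test_that("UPGMA reproduces the closed-form three-taxon tree and ultrametrics", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_tree(d, "upgma")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  cd <- as.matrix(ape::cophenetic.phylo(tr))[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(cd, d)
  # random ultrametric input is reproduced exactly
  set.seed(12)
  h <- hclust(dist(matrix(rnorm(30), 10)), method = "average")
  du <- as.matrix(cophenetic(h))
  tru <- build_tree(du, "upgma")
  expect_equal(as.matrix(ape::cophenetic.phylo(tru))[rownames(du), colnames(du)],
               du, tolerance = 1e-10)
  expect_error(build_tree(d[1:2, 1:2], "upgma"), "3 taxa")
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(14)
  tr0 <- ape::rtree(12)
  d <- as.matrix(ape::cophenetic.phylo(tr0))
  tr <- build_tree(d, "nj")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), ape::unroot(tr))), 0)
})
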