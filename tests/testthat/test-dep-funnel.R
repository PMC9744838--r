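test_that("accession-to-gene mapping dedups and tracks unmapped", {
  m <- c(Q14566 = "MCM6", P25205 = "MCM3", X1 = "MCM6")
  r <- mapToGenes("Q14566", m)
  expect_equal(r$genes, "MCM6")
  expect_length(r$unmapped, 0)

  r2 <- mapToGenes(c("Q14566", "X1"), m)
  expect_equal(r2$genes, "MCM6")  # two accessions, one gene

  r3 <- mapToGenes(c("Q14566", "NOPE"), m)
  expect_equal(r3$unmapped, "NOPE")
  expect_error(mapToGenes("A", character()), "empty")
})

.mkFC <- function(acc, dir) {
  data.frame(accession = acc, gene = "", nsaf_control = 0.01,
             nsaf_treated = 0.04, fc = 4, log2fc = 2,
             direction = dir, stringsAsFactors = FALSE)
}

test_that("the staged funnel intersects sequentially", {
  mapping <- setNames(paste0("G", 1:10), paste0("P", 1:10))
  fc <- .mkFC(paste0("P", 1:10), "up")
  stages <- list(s1 = paste0("G", 1:6), s2 = paste0("G", c(1:3, 6)),
                 s3 = paste0("G", 1:3))
  out <- runFunnel(fc, stages, mapping)
  expect_equal(out$stages$n_retained, c(10, 6, 4, 3))
  expect_setequal(out$genes$s3, paste0("G", 1:3))

  sup <- runFunnel(fc, list(all = paste0("G", 1:10)), mapping)
  expect_equal(sup$stages$n_retained[2], 10)

  disj <- runFunnel(fc, list(none = "ZZZ", later = paste0("G", 1:5)),
                    mapping)
  expect_equal(disj$stages$n_retained[2:3], c(0, 0))

  expect_error(runFunnel(fc, list(bad = character()), mapping), "bad")
})

test_that("funnel sizes are non-increasing and order-independent at the end", {
  set.seed(77)
  mapping <- setNames(paste0("G", 1:40), paste0("P", 1:40))
  fc <- .mkFC(paste0("P", 1:40), sample(c("up", "down"), 40, TRUE))
  stages <- list(a = sample(paste0("G", 1:40), 25),
                 b = sample(paste0("G", 1:40), 20),
                 c = sample(paste0("G", 1:40), 15))
  out <- runFunnel(fc, stages, mapping)
  sizes <- out$stages$n_retained
  expect_true(all(diff(sizes) <= 0))
  perm <- runFunnel(fc, stages[c(3, 1, 2)], mapping)
  expect_setequal(out$genes[[length(out$genes)]],
                  perm$genes[[length(perm$genes)]])
})

test_that("unchanged proteins never enter the funnel", {
  mapping <- c(P1 = "G1", P2 = "G2")
  fc <- rbind(.mkFC("P1", "up"), .mkFC("P2", "unchanged"))
  out <- runFunnel(fc, list(all = c("G1", "G2")), mapping)
  expect_equal(out$genes$selected, "G1")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # closed-form check: N=10, K=5, n=4, k=4 -> C(5,4)/C(10,4) = 5/210
  uni <- paste0("g", 1:10)
  coll <- list(hit = uni[1:5])
  r <- hypergeomEnrich(uni[1:4], uni, coll, adjust = "none")
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)

  set.seed(99)
  for (i in 1:30) {
    N <- sample(5:20, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    uni <- paste0("g", seq_len(N))
    query <- sample(uni, n)
    k <- sum(query %in% uni[seq_len(K)])
    got <- hypergeomEnrich(query, uni, list(s = uni[seq_len(K)]),
                           adjust = "none")
    want <- if (k == 0) 1 else oracleHyper(N, K, n, k)
    expect_equal(got$p, want, tolerance = 1e-10,
                 info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
})

test_that("enrichment edge cases: certain events and empty overlap", {
  uni <- paste0("g", 1:8)
  all <- hypergeomEnrich(uni, uni, list(s = uni), adjust = "none")
  expect_equal(all$p, 1)
  expect_equal(all$k, all$n)

  disj <- hypergeomEnrich(uni[1:3], uni, list(s = "OTHER"),
                          adjust = "none")
  expect_equal(disj$p, 1)
  expect_equal(disj$k, 0)

  expect_error(hypergeomEnrich(paste0("g", 1:9), paste0("g", 1:3),
                               list(s = "g1")), "universe")
  expect_warning(hypergeomEnrich(c("g1", "zz"), uni, list(s = "g1"),
                                 adjust = "none"), "dropped")
})

test_that("p is non-increasing in the overlap and BH behaves", {
  N <- 40; K <- 12; n <- 10
  uni <- paste0("g", seq_len(N))
  ps <- vapply(1:min(K, n), function(k) {
    filler <- if (n - k > 0) uni[(K + 1):(K + n - k)] else character()
    query <- c(uni[seq_len(k)], filler)
    hypergeomEnrich(query, uni, list(s = uni[seq_len(K)]),
                    adjust = "none")$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))

  set.seed(4)
  coll <- lapply(1:6, function(i) sample(uni, 8))
  names(coll) <- paste0("s", 1:6)
  r <- hypergeomEnrich(sample(uni, 10), uni, coll, adjust = "BH")
  expect_true(all(r$p_adj >= r$p - 1e-15))
  expect_true(all(r$p_adj <= 1))
  expect_equal(order(r$p), order(r$p_adj))  # BH preserves p-order
  expect_equal(r$p_adj, p.adjust(r$p, "BH"))
})

test_that("per-repeat set-overlap profiles report mean and SD", {
  coll <- list(s = c("A", "B"))
  same <- enrichmentProfile(list(c("A", "C"), c("A", "C")), coll)
  expect_equal(same$sd_fraction, 0)

  two <- enrichmentProfile(list(c("A", "X", "Y", "Z", "W"),
                                c("A", "B", "X", "Y", "Z")), coll)
  expect_equal(two$mean_fraction, 0.3)
  expect_equal(two$sd_fraction, sd(c(0.2, 0.4)), tolerance = 1e-12)

  none <- enrichmentProfile(list(c("Q"), c("R")), coll)
  expect_equal(none$mean_fraction, 0)

  single <- enrichmentProfile(list(c("A")), coll)
  expect_true(is.na(single$sd_fraction))
})
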