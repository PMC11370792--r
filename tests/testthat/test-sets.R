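test_that("Venn partition enumerates membership patterns exactly", {
  expect_error(partitionUniqueShared(list(A = "a")), "invalid argument")

  disj <- partitionUniqueShared(list(A = "a", B = "b", C = "c"))
  expect_equal(unname(disj[c("A", "B", "C")]), c(1L, 1L, 1L))
  expect_length(disj, 3)

  same <- partitionUniqueShared(list(A = letters[1:4], B = letters[1:4],
                                     C = letters[1:4]))
  expect_equal(unname(same[["A&B&C"]]), 4L)
  expect_length(same, 1)

  # random 3-set instance equals a brute-force membership tally
  set.seed(1)
  sets <- lapply(1:3, function(i) sample(letters[1:26], 12))
  names(sets) <- c("X", "Y", "Z")
  part <- partitionUniqueShared(sets)
  expect_equal(sum(part), length(unique(unlist(sets))))
  for (g in unique(unlist(sets))) {
    pat <- paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
                 collapse = "&")
    expect_true(pat %in% names(part))
  }
  # order invariance
  expect_equal(sort(part),
               sort(partitionUniqueShared(rev(sets))))
})

test_that("uniqueness index is the unique/shared count ratio", {
  part <- c(A = 2L, B = 2L, C = 2L, "A&B" = 1L, "B&C" = 1L, "A&C" = 1L,
            "A&B&C" = 3L)
  expect_equal(uniquenessIndex(part), 1.0)
  expect_true(is.na(uniquenessIndex(c(A = 5L, B = 2L, C = 1L))))

  sets <- list(A = c("a", "b", "s"), B = c("c", "s"), C = c("d", "s"))
  # by hand: unique a,b,c,d = 4; shared s (triple) = 1
  expect_equal(uniquenessIndex(sets), 4)
})

test_that("threshold sweep emits the full table and a plateau-based tau*", {
  mkTable <- function(r, p) data.frame(gene = names(r), r = r, pEmp = p,
                                       pFdr = p, sign = "positive",
                                       selected = TRUE)
  genes <- paste0("g", 1:50)
  # genes 1-10: weakly shared by all maps; 11-20: strongly shared;
  # 21-50: strongly correlated in exactly one map each. The r values sit
  # strictly between grid points so boundary ties cannot occur.
  rA <- setNames(c(rep(0.17, 10), rep(0.47, 10), rep(0.47, 10), rep(0, 20)),
                 genes)
  rB <- setNames(c(rep(0.17, 10), rep(0.47, 10), rep(0, 10), rep(0.47, 10),
                   rep(0, 10)), genes)
  rC <- setNames(c(rep(0.17, 10), rep(0.47, 10), rep(0, 20), rep(0.47, 10)),
                 genes)
  p <- setNames(rep(0.001, 50), genes)
  tabs <- list(A = mkTable(rA, p), B = mkTable(rB, p), C = mkTable(rC, p))
  sw <- thresholdSweep(tabs, tauGrid = seq(0, 0.5, 0.05))
  expect_equal(nrow(sw), 11)
  # verify tau* against a by-hand recomputation from the emitted table
  target <- 0.9 * max(sw$U, na.rm = TRUE)
  expect_equal(attr(sw, "tauStar"),
               min(sw$tau[!is.na(sw$U) & sw$U >= target]))
  # below 0.2 the weak shared genes keep U low; above they drop out
  expect_equal(attr(sw, "tauStar"), 0.2)
  expect_true(all(diff(sw$n_A) <= 0))  # selections shrink as tau rises

  one <- thresholdSweep(tabs, tauGrid = 0.3)
  expect_equal(attr(one, "tauStar"), 0.3)

  # all-undefined U: every gene shared
  tabsS <- list(A = mkTable(rA[1:10], p[1:10]), B = mkTable(rA[1:10], p[1:10]),
                C = mkTable(rA[1:10], p[1:10]))
  swS <- thresholdSweep(tabsS, tauGrid = c(0.5))
  expect_true(is.na(attr(swS, "tauStar")))
})

test_that("Fisher overlap equals exhaustive hypergeometric enumeration", {
  bg <- letters[1:10]
  f <- fisherOverlap(bg[1:4], bg[c(1:3, 5, 6)], bg)
  expect_equal(f$overlap, 3)
  expect_equal(f$p, bruteHypergeomTail(10, 4, 5, 3))

  # zero overlap has p = 1
  f0 <- fisherOverlap(bg[1:2], bg[3:4], bg)
  expect_equal(f0$p, 1)

  expect_error(fisherOverlap(character(0), bg[1:2], bg), "empty set")
  expect_error(fisherOverlap(c("zz"), bg[1:2], bg), "universe violation")

  # all tables with N <= 12
  for (N in 2:12) {
    bgN <- as.character(seq_len(N))
    for (a in 1:(N - 1)) for (b in 1:(N - 1)) {
      maxOv <- min(a, b)
      minOv <- max(0, a + b - N)
      for (ov in unique(c(minOv, maxOv))) {
        A <- bgN[1:a]
        B <- bgN[c(seq_len(ov), setdiff(seq_len(N), 1:a))[1:b]]
        B <- unique(c(bgN[seq_len(ov)], setdiff(bgN, A)))[1:b]
        got <- fisherOverlap(A, B, bgN)
        expect_equal(got$p,
                     bruteHypergeomTail(N, a, b, got$overlap),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("proportion chi-square is uncorrected Pearson on the 2x2 table", {
  expect_equal(chisqProportions(146, 257, 88, 257)$statistic, 26.39,
               tolerance = 0.01 / 26.39)
  expect_equal(chisqProportions(37, 1373, 42, 1353)$statistic, 0.41,
               tolerance = 0.03)
  expect_equal(chisqProportions(10, 100, 10, 100)$statistic, 0)
  # symmetry in group order
  expect_equal(chisqProportions(20, 50, 9, 40)$statistic,
               chisqProportions(9, 40, 20, 50)$statistic)
  expect_error(chisqProportions(0, 10, 0, 10), "degenerate table")
  # the Yates-corrected variant is available but differs
  expect_lt(chisqProportions(146, 257, 88, 257, correct = TRUE)$statistic,
            26.39)
})

test_that("resampling null converges to the exact subset enumeration", {
  pool <- letters[1:8]
  query <- letters[c(1, 2, 9)]
  subsets <- combn(8, 3)
  exact <- apply(subsets, 2, function(s) sum(pool[s] %in% query))
  res <- resampleOverlapNull(pool, 3, query, B = 4000, observed = 2,
                             direction = "greater", seed = 5)
  expect_lt(abs(res$p - mean(exact >= 2)), 0.03)
  expect_lt(abs(mean(res$null) - mean(exact)), 0.05)

  # degenerate draws and disjoint queries
  degen <- resampleOverlapNull(pool, 8, query, B = 50, observed = 0, seed = 1)
  expect_true(all(degen$null == 2))
  disj <- resampleOverlapNull(pool, 3, c("x", "y"), B = 50, observed = 0,
                              seed = 1)
  expect_true(all(disj$null == 0))
  expect_error(resampleOverlapNull(pool, 9, query, observed = 0), "invalid argument")
})

test_that("length matching is greedy nearest-neighbour without replacement", {
  q <- c(q1 = 100, q2 = 1000, q3 = 50000)
  cand <- c(c1 = 100, c2 = 1000, c3 = 50000, c4 = 7, c5 = 2e6)
  m <- matchByLength(q, cand)
  expect_equal(unname(m[c("q1", "q2", "q3")]), c("c1", "c2", "c3"))
  expect_length(m, length(q))
  expect_error(matchByLength(q, cand[1:2]), "insufficient candidates")

  # deterministic, and never cheaper than the optimal assignment
  set.seed(6)
  q2 <- setNames(exp(runif(6, 3, 10)), paste0("q", 1:6))
  c2 <- setNames(exp(runif(10, 3, 10)), paste0("c", 1:10))
  m1 <- matchByLength(q2, c2)
  expect_identical(m1, matchByLength(q2, c2))
  cost <- function(assign) sum(abs(log(q2) - log(c2[assign])))
  perms <- combn(10, 6)
  best <- Inf
  for (k in seq_len(ncol(perms))) {
    # minimal cost over candidate subsets with optimal within-subset pairing
    sub <- perms[, k]
    o <- order(log(c2[sub]))
    best <- min(best, sum(abs(sort(log(q2)) - sort(log(c2[sub])))))
  }
  expect_gte(cost(m1), best - 1e-12)
})

test_that("over-representation analysis applies Holm across terms", {
  bg <- paste0("g", 1:100)
  query <- bg[1:10]
  coll <- list(hit = bg[1:12], part = bg[5:40], none = bg[60:80],
               all = bg, tiny = bg[1:2])
  res <- oraCollections(query, coll, bg)
  expect_equal(res$term[1], "hit")
  expect_equal(res$pHolm, bruteHolm(res$p)[order(res$p)][rank(res$p)],
               tolerance = 1e-12)
  # single term: Holm equals raw
  one <- oraCollections(query, coll["hit"], bg)
  expect_equal(one$pHolm, one$p)
  expect_error(oraCollections(character(0), coll, bg), "empty set")
})
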