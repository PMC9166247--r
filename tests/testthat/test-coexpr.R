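test_that("Pearson r and p match hand computation and limits", {
  o <- pearsonWithP(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(o$r, 6.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_equal(o$p, 0.0172923702, tolerance = 1e-8)
  x <- c(2, 4, 5, 9)
  self <- pearsonWithP(x, x)
  expect_equal(self$r, 1)
  expect_equal(self$p, 0)
  neg <- pearsonWithP(x, -3 * x + 2)
  expect_equal(neg$r, -1)
  expect_equal(neg$p, 0)
  expect_error(pearsonWithP(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearsonWithP(1:2, 1:2), "at least 3")
})

test_that("Pearson p matches cor.test on random instances", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- pearsonWithP(x, y)
    ref <- oracleCor(x, y)
    expect_equal(mine$r, ref$r, tolerance = 1e-10)
    expect_equal(mine$p, ref$p, tolerance = 1e-10)
  }
})

test_that("correlation p agrees with a permutation null", {
  # at n = 30 the t-transform p and the conditional permutation p agree to
  # Monte-Carlo error; at n = 10 the permutation distribution carries a
  # genuine O(1/n) difference from the t reference, so that check gets an
  # explicit small-sample allowance on top of the MC band
  set.seed(21)
  nPerm <- 10000
  permP <- function(x, y) {
    r0 <- abs(cor(x, y))
    (sum(replicate(nPerm, abs(cor(x, sample(y))) >= r0)) + 1) / (nPerm + 1)
  }
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    p <- pearsonWithP(x, y)$p
    se <- sqrt(max(p * (1 - p), 1e-6) / nPerm)
    expect_lt(abs(permP(x, y) - p), 3 * se + 2 / nPerm)
  }
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    p <- pearsonWithP(x, y)$p
    se <- sqrt(max(p * (1 - p), 1e-6) / nPerm)
    expect_lt(abs(permP(x, y) - p), 3 * se + 0.06)
  }
})

test_that("network construction matches the brute-force all-pairs oracle", {
  for (seed in 1:3) {
    sim <- simulateBulk(nGenes = 50, nLnc = 10, hubDegree = 6,
                        deFrac = 0.3, seed = seed)
    bt <- rowData(sim$expr)$biotype
    lnc <- rownames(sim$expr)[bt == "lncRNA"]
    mrna <- rownames(sim$expr)[bt == "mRNA"]
    net <- suppressWarnings(buildNetwork(sim$expr, lnc, mrna))
    ref <- oracleNetwork(assay(sim$expr, 1), lnc, mrna)
    ed <- as.data.frame(netEdges(net))
    expect_equal(nrow(ed), nrow(ref))
    expect_equal(ed$lnc, ref$lnc)
    expect_equal(ed$mrna, ref$mrna)
    expect_equal(ed$r, ref$r, tolerance = 1e-12)
    # degree handshake and bipartite split equality
    nd <- netNodes(net)
    expect_equal(sum(nd$degree), 2L * nrow(ed))
    expect_equal(sum(nd$degree[nd$biotype == "lncRNA"]), nrow(ed))
    expect_equal(sum(nd$degree[nd$biotype == "mRNA"]), nrow(ed))
    expect_true(all(nd$degree >= 1L))
  }
})

test_that("edges respect strict thresholds and threshold monotonicity", {
  sim <- simulateBulk(nGenes = 60, nLnc = 10, hubDegree = 6, seed = 8)
  bt <- rowData(sim$expr)$biotype
  lnc <- rownames(sim$expr)[bt == "lncRNA"]
  mrna <- rownames(sim$expr)[bt == "mRNA"]
  net <- suppressWarnings(buildNetwork(sim$expr, lnc, mrna))
  ed <- netEdges(net)
  expect_true(all(abs(ed$r) > 0.8 & ed$p < 0.01))
  expect_equal(ed$sign == "positive", ed$r > 0)
  # raising the r threshold never adds edges
  tight <- suppressWarnings(buildNetwork(sim$expr, lnc, mrna,
                                         rThreshold = 0.9))
  key <- function(e) paste(e$lnc, e$mrna)
  expect_true(all(key(netEdges(tight)) %in% key(ed)))
  # r threshold 1.0 retains nothing on noisy data
  none <- suppressWarnings(buildNetwork(sim$expr, lnc, mrna,
                                        rThreshold = 1.0))
  expect_equal(length(none), 0L)
  # edge set invariant to row permutation of the input
  perm <- sim$expr[sample(nrow(sim$expr)), ]
  net2 <- suppressWarnings(buildNetwork(perm, lnc, mrna))
  expect_equal(as.data.frame(netEdges(net2)), as.data.frame(ed))
})

test_that("constant genes are skipped with a warning, empty sets warn", {
  sim <- simulateBulk(nGenes = 30, nLnc = 3, hubDegree = 2, seed = 10)
  m <- assay(sim$expr, 1)
  m["LNC001", ] <- 5
  se <- makeBulkExperiment(m, setNames(colData(sim$expr)$group, colnames(m)),
                           setNames(rowData(sim$expr)$biotype, rownames(m)))
  expect_warning(net <- buildNetwork(se, c("LNC001", "LNC002"),
                                     rownames(m)[4:30]),
                 "constant")
  expect_false("LNC001" %in% netNodes(net)$id)
  expect_warning(empty <- buildNetwork(sim$expr, character(),
                                       rownames(m)[4:10]), "empty")
  expect_equal(length(empty), 0L)
})

test_that("degree table orders, breaks ties lexicographically and filters", {
  ed <- data.frame(lnc = c("L1", "L1", "L1", "L2"),
                   mrna = c("M1", "M2", "M3", "M1"))
  net <- makeNet(ed)
  dt <- degreeTable(net)
  expect_equal(dt$node, c("L1", "M1", "L2", "M2", "M3"))
  expect_equal(dt$degree, c(3L, 2L, 1L, 1L, 1L))
  shown <- degreeTable(net, minDegreeShown = 2)
  expect_equal(shown$node, "L1")
  expect_equal(hubGenes(net), "L1")
  empty <- makeNet(data.frame(lnc = character(), mrna = character()))
  expect_equal(nrow(degreeTable(empty)), 0L)
  expect_equal(hubGenes(empty), character())
})

test_that("hub subnetwork is the induced first neighborhood", {
  star <- makeNet(data.frame(lnc = c("L1", "L1", "L1"),
                             mrna = c("M1", "M2", "M3")))
  sub <- hubSubnetwork(star, "L1")
  expect_equal(nrow(netNodes(sub)), 4L)
  expect_equal(length(sub), 3L)
  # edges among the neighborhood are retained, edges leaving it are not
  ed <- data.frame(lnc = c("L1", "L1", "L2"), mrna = c("M1", "M2", "M1"))
  sub2 <- hubSubnetwork(makeNet(ed), "M1")
  expect_equal(sort(netNodes(sub2)$id), c("L1", "L2", "M1"))
  expect_equal(length(sub2), 2L)  # L1-M2 dropped: M2 outside the ball
  expect_error(hubSubnetwork(star, "ABSENT"), "not in the network")
})

test_that("a strongly correlated planted module is retained in full", {
  # effectSize = 0 isolates the latent-factor correlation: the pooled and
  # within-group correlations coincide at rhoTarget
  sim <- simulateBulk(nGenes = 120, nLnc = 12, hubDegree = 10,
                      effectSize = 0, rhoTarget = 0.95, seed = 13)
  bt <- rowData(sim$expr)$biotype
  net <- suppressWarnings(
    buildNetwork(sim$expr, rownames(sim$expr)[bt == "lncRNA"],
                 rownames(sim$expr)[bt == "mRNA"]))
  hub <- names(sim$truth@hubLncs)
  ed <- netEdges(net)
  expect_setequal(ed$mrna[ed$lnc == hub], sim$truth@hubLncs[[1]])
  nd <- netNodes(net)
  expect_equal(nd$degree[nd$id == hub], 10L)
})

test_that("the planted hub yields the expected 29-gene subnetwork", {
  sim <- simulateBulk(nGenes = 500, nLnc = 50, hubDegree = 28, seed = 3)
  deg <- runComparison(sim$expr, "IPF", "normal")
  ipf <- intersectComparisons(list(deg))
  net <- suppressWarnings(buildNetwork(sim$expr, ipf$lnc, ipf$mrna,
                                       list(deg)))
  hub <- names(sim$truth@hubLncs)
  expect_equal(hubGenes(net, "lncRNA"), hub)
  # the full degree table's top entry is the hub gene
  expect_equal(degreeTable(net)$node[1L], hub)
  sub <- hubSubnetwork(net, hub)
  expect_equal(nrow(netNodes(sub)), 29L)
  # regulation labels copied from the DEG table
  expect_equal(unique(netNodes(sub)$regulation), "up")
})
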