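test_that("reversal distance matches frozen worked examples", {
  po <- permOrders(c(1L, -3L, -2L))
  expect_equal(reversalDistance(po$src, po$tgt), 1L)
  po2 <- permOrders(c(2L, 1L))
  expect_equal(reversalDistance(po2$src, po2$tgt), 3L)  # BFS-derived
  id <- permOrders(1:4)
  expect_equal(reversalDistance(id$src, id$tgt), 0L)
})

test_that("reversal distance equals the BFS oracle exhaustively for n <= 3", {
  for (n in 1:3) {
    idx <- expand.grid(rep(list(seq_len(n)), n))
    idx <- idx[apply(idx, 1, function(r) length(unique(r)) == n), ,
               drop = FALSE]
    signsAll <- expand.grid(rep(list(c(-1L, 1L)), n))
    for (r in seq_len(nrow(idx))) for (s in seq_len(nrow(signsAll))) {
      p <- as.integer(idx[r, ]) * as.integer(signsAll[s, ])
      po <- permOrders(p)
      expect_equal(reversalDistance(po$src, po$tgt),
                   bfsReversalDistance(p),
                   info = paste(p, collapse = ","))
    }
  }
})

test_that("distance is symmetric and satisfies the triangle inequality", {
  set.seed(11)
  mkPerm <- function(n) sample(n) * sample(c(-1L, 1L), n, TRUE)
  for (rep in 1:10) {
    n <- 5L
    labels <- paste0("g", 1:n)
    ords <- lapply(1:3, function(i) {
      p <- mkPerm(n)
      sgo(paste0(ifelse(p > 0, "+", "-"), labels[abs(p)]))
    })
    d12 <- reversalDistance(ords[[1]], ords[[2]])
    d21 <- reversalDistance(ords[[2]], ords[[1]])
    d13 <- reversalDistance(ords[[1]], ords[[3]])
    d23 <- reversalDistance(ords[[2]], ords[[3]])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23)
  }
})

test_that("breakpoint counts follow the adjacency-set definition", {
  a <- sgo(paste0("+", letters[1:6]), circular = TRUE)
  expect_equal(breakpointCount(a, a), 0L)
  ## one internal inversion of a circular order creates two breakpoints
  b <- sgo(c("+a", "-d", "-c", "-b", "+e", "+f"), circular = TRUE)
  expect_equal(breakpointCount(b, a), 2L)
  ## rotation/reflection equivalence detected as zero breakpoints
  rot <- sgo(c("+c", "+d", "+e", "+f", "+a", "+b"), circular = TRUE)
  expect_equal(breakpointCount(rot, a), 0L)
  refl <- sgo(paste0("-", rev(letters[1:6])), circular = TRUE)
  expect_equal(breakpointCount(refl, a), 0L)

  ## random orders vs direct adjacency enumeration
  set.seed(5)
  adjOracle <- function(x, y) {
    pairs <- function(o) {
      n <- length(o@blocks)
      i <- seq_len(n); j <- c(2:n, 1L)
      lab <- function(k, flip)
        paste0(ifelse(xor(o@signs[k] < 0, flip), "-", "+"), o@blocks[k])
      unique(c(paste(lab(i, FALSE), lab(j, FALSE)),
               paste(lab(j, TRUE), lab(i, TRUE))))
    }
    n <- length(x@blocks)
    px <- pairs(x)[seq_len(n)]
    sum(!(px %in% pairs(y)))
  }
  for (rep in 1:20) {
    p <- sample(8) * sample(c(-1L, 1L), 8, TRUE)
    x <- sgo(paste0(ifelse(p > 0, "+", "-"), letters[abs(p)]),
             circular = TRUE)
    y <- sgo(paste0("+", letters[1:8]), circular = TRUE)
    expect_equal(breakpointCount(x, y), adjOracle(x, y))
  }
})

test_that("distance respects the breakpoint lower bound and replay invariant", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(4:6, 1)
    p <- sample(n) * sample(c(-1L, 1L), n, TRUE)
    src <- sgo(paste0(ifelse(p > 0, "+", "-"), paste0("g", abs(p))),
               circular = TRUE)
    tgt <- sgo(paste0("+g", 1:n), circular = TRUE)
    d <- reversalDistance(src, tgt)
    b <- breakpointCount(src, tgt)
    expect_gte(d, ceiling(b / 2))
    sc <- inferInversionScenario(src, tgt)
    expect_equal(sc@distance, d)
    out <- replayScenario(src, sc)
    expect_equal(breakpointCount(out, tgt), 0L)
  }
})

test_that("strip collapse merges shared runs and extracts tandem duplicates", {
  a <- sgo(paste0("+", letters[1:10]), circular = TRUE)
  cb <- collapseToBlocks(a, a)
  expect_equal(length(blocks(cb$source)), 1L)

  b <- sgo(c("+a", "+b", "-c", "+d", "+e", "+f", "+g", "+h", "+i", "+j"),
           circular = TRUE)
  cb2 <- collapseToBlocks(b, a)
  expect_equal(length(blocks(cb2$source)), 3L)
  expect_setequal(blocks(cb2$source), blocks(cb2$target))

  dup <- sgo(c("+a", "+b", "+b#1", "+c"), circular = TRUE)
  ref <- sgo(c("+a", "+b", "+c"), circular = TRUE)
  cb3 <- collapseToBlocks(dup, ref)
  expect_equal(cb3$duplications$block, "b")
  expect_equal(cb3$duplications$placement, "tandem")

  far <- sgo(c("+a", "+b", "+c", "+d", "+b#1", "+e"), circular = TRUE)
  expect_error(collapseToBlocks(far, sgo(paste0("+", letters[1:5]),
                                         circular = TRUE)),
               "non-tandem")
})

test_that("published-order encodings give the narrated minimal scenarios", {
  path <- system.file("extdata", "gene_orders_published.txt",
                      package = "plastevol")
  pub <- readGeneOrders(path)
  anc <- pub$Ancestor

  skra <- inferInversionScenario(anc, pub$Skra)
  expect_equal(skra@distance, 1L)
  expect_true(scenarioEvents(skra)[[1]]$spansRepeat)
  expect_equal(skra@orientationTrajectory, c("IR", "DR"))

  iso <- inferInversionScenario(anc, pub$Iso)
  expect_equal(iso@distance, 2L)
  expect_equal(iso@orientationTrajectory, c("IR", "DR", "IR"))

  for (sp in c("Smoe", "Slep", "Stam"))
    expect_equal(reversalDistance(anc, pub[[sp]]), 2L, info = sp)

  ## S. uncinata needs the tandem duplication removed first, then >= 5
  cb <- collapseToBlocks(anc, pub$Sunc)
  expect_equal(cb$duplications$placement, c("tandem", "tandem"))
  d <- reversalDistance(cb$source, cb$target, maxEvents = 7L)
  expect_gte(d, 5L)
  sunc <- inferInversionScenario(cb$source, cb$target, maxEvents = 7L)
  spans <- vapply(scenarioEvents(sunc), `[[`, TRUE, "spansRepeat")
  expect_equal(sum(spans) %% 2L, 0L)     # IR -> IR parity
})

test_that("orientation parity matches the IR/DR difference on random histories", {
  set.seed(41)
  base <- sgo(c("+a", "+b", "+c", "+REP", "+d", "+e", "+f"),
              circular = TRUE, flag = "IR")
  for (rep in 1:10) {
    cur <- base
    k <- sample(1:3, 1)
    for (e in seq_len(k)) {
      m <- length(blocks(cur))
      ij <- sort(sample(2:m, 2))
      rpos <- match("REP", blocks(cur))
      spans <- rpos >= ij[1] && rpos <= ij[2]
      cur <- replayScenario(cur, new("InversionScenario",
        events = list(list(interval = ij, spansRepeat = spans,
                           label = "")),
        distance = 1L, breakpointsInitial = 0L,
        orientationTrajectory = character(0), optimal = TRUE,
        coOptima = list()))
    }
    sc <- inferInversionScenario(base, cur)
    spans <- vapply(scenarioEvents(sc), `[[`, TRUE, "spansRepeat")
    flip <- sum(spans) %% 2L == 1L
    expect_equal(flip, orientationFlag(cur) != "IR")
    if (length(sc@orientationTrajectory))
      expect_equal(tail(sc@orientationTrajectory, 1),
                   orientationFlag(cur))
  }
})

test_that("events are placed on the deepest consistent branches", {
  path <- system.file("extdata", "gene_orders_published.txt",
                      package = "plastevol")
  pub <- readGeneOrders(path)
  tr <- ape::read.tree(text =
    "(Out,(Skra,(Slep,(Smoe,Stam)))Selaginella);")
  tipOrders <- list(Out = pub$Ancestor, Skra = pub$Skra,
                    Slep = pub$Slep, Smoe = pub$Smoe, Stam = pub$Stam)
  placed <- placeEventsOnTree(pub$Ancestor, tipOrders, tr,
                              maxEvents = 7L, cap = 24L)
  ## the shared spanning inversion lands on the Selaginella stem branch
  stemEvents <- placed[placed$branch == "Selaginella", ]
  expect_equal(nrow(stemEvents), 1L)
  expect_true(stemEvents$spansRepeat)
  ## total events strictly fewer than independent pairwise scenarios
  indep <- sum(vapply(names(tipOrders), function(tp)
    reversalDistance(pub$Ancestor, tipOrders[[tp]], maxEvents = 7L), 1L))
  expect_lt(nrow(placed), indep)
})

test_that("private tip events land on terminal branches", {
  anc <- sgo(c("+a", "+b", "+c", "+d", "+e", "+f"), circular = TRUE)
  shared <- replayScenario(anc, new("InversionScenario",
    events = list(list(interval = c(2, 4), spansRepeat = FALSE,
                       label = "")),
    distance = 1L, breakpointsInitial = 0L,
    orientationTrajectory = character(0), optimal = TRUE,
    coOptima = list()))
  t3 <- replayScenario(shared, new("InversionScenario",
    events = list(list(interval = c(5, 6), spansRepeat = FALSE,
                       label = "")),
    distance = 1L, breakpointsInitial = 0L,
    orientationTrajectory = character(0), optimal = TRUE,
    coOptima = list()))
  tr <- ape::read.tree(text = "(out,(A,B));")
  placed <- placeEventsOnTree(anc, list(out = anc, A = shared, B = t3),
                              tr)
  expect_equal(sum(placed$branch == "B"), 1L)
  ## the shared event sits on the (A,B) stem, not twice on terminals
  expect_equal(nrow(placed), 2L)
})
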