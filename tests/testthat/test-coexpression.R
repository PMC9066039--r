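test_that("TOM matches the hand-looped formula and structural properties", {
  set.seed(19)
  m <- matrix(rnorm(4 * 10), 4, 10, dimnames = list(paste0("f", 1:4), NULL))
  tom <- tom_from_expression(m, power = 2)
  expect_equal(unname(tom), tom_oracle(m, 2), tolerance = 1e-12)
  expect_true(isSymmetric(tom))
  expect_equal(unname(diag(tom)), rep(1, 4))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))

  # identical profiles -> adjacency 1 -> TOM 1
  dup <- rbind(a = m[1, ], b = m[1, ])
  tom2 <- tom_from_expression(dup, power = 6)
  expect_equal(tom2["a", "b"], 1)

  mm <- rbind(m, const = rep(1, 10))
  expect_warning(tom3 <- tom_from_expression(mm, 2), "constant")
  expect_equal(nrow(tom3), 4)
})

test_that("soft power qualifies on modular data and falls back on noise", {
  set.seed(27)
  mod <- do.call(rbind, lapply(c(40, 25, 15, 10, 5), function(sz) {
    lat <- rnorm(15)
    t(vapply(seq_len(sz), function(i) {
      w <- runif(1, 0.3, 0.95)
      sqrt(w) * lat + sqrt(1 - w) * rnorm(15)
    }, numeric(15)))
  }))
  mod <- rbind(mod, matrix(rnorm(60 * 15), 60, 15))
  p <- pick_soft_power(mod)
  fits <- attr(p, "fits")
  expect_gte(fits$r2[fits$power == p], 0.8)
  # fit statistics equal an independent recomputation from the adjacency
  a <- abs(cor(t(mod)))^p; diag(a) <- 0
  k <- rowSums(a)
  expect_equal(fits$k_mean[fits$power == p], mean(k), tolerance = 1e-12)

  set.seed(28)
  noise <- matrix(rnorm(100 * 15), 100, 15)
  expect_warning(pn <- pick_soft_power(noise), "falling back")
  expect_equal(as.integer(pn), 6L)
  expect_error(pick_soft_power(noise[1:2, ]), "at least 3")
})

test_that("module detection recovers planted blocks and rejects noise", {
  set.seed(35)
  m <- rbind(make_block(30, 0.9), make_block(30, 0.9))
  rownames(m) <- paste0("f", 1:60)
  tom <- tom_from_expression(m, 6)
  lab <- detect_modules(tom, min_module_size = 5)
  expect_gte(ari(lab, rep(1:2, each = 30)), 0.8)
  # deterministic given the matrix
  expect_identical(lab, detect_modules(tom, min_module_size = 5))

  unassigned <- vapply(1:5, function(s) {
    set.seed(100 + s)
    nz <- matrix(rnorm(60 * 15), 60, 15,
                 dimnames = list(paste0("n", 1:60), NULL))
    w <- getOption("warn"); options(warn = -1); on.exit(options(warn = w))
    mean(detect_modules(tom_from_expression(nz, 6), 5) == 0)
  }, 0.0)
  expect_gte(mean(unassigned), 0.8)
})

test_that("eigengene tracks planted members and orientation is stable", {
  set.seed(55)
  m <- make_block(20, 0.95)
  rownames(m) <- paste0("f", 1:20)
  eg <- module_eigengene(m, rownames(m))
  cors <- apply(m, 1, cor, y = eg)
  expect_gte(min(abs(cors)), 0.9)
  expect_gte(mean(cors), 0)  # sign-oriented toward the members
  # flipping all member profiles leaves |correlation| unchanged
  eg2 <- module_eigengene(-m, rownames(m))
  expect_equal(abs(cor(eg, eg2)), 1, tolerance = 1e-8)
})

test_that("a module tracking day +1 is associated with that stage", {
  set.seed(65)
  design <- data.frame(sample_id = paste0("s", 1:15),
                       individual = rep(c("I1", "I2", "I3"), each = 5),
                       stage = rep(c("-14", "-10", "-6", "-2", "+1"), 3))
  up <- as.numeric(design$stage == "+1")
  block <- t(vapply(1:12, function(i) 2 * up + rnorm(15, 0, 0.4),
                    numeric(15)))
  other <- matrix(rnorm(20 * 15), 20, 15)
  m <- rbind(block, other)
  rownames(m) <- paste0("f", 1:32)
  colnames(m) <- design$sample_id
  labels <- setNames(c(rep(1L, 12), rep(0L, 20)), rownames(m))
  assoc <- module_trait_association(labels, m, design)
  expect_lt(assoc$p["ME1", "+1"], 0.05)
  expect_gt(assoc$r["ME1", "+1"], 0)
  # symmetry: flipping every member's sign leaves |r| unchanged
  assoc2 <- module_trait_association(labels, -m, design)
  expect_equal(abs(assoc2$r), abs(assoc$r), tolerance = 1e-8)
})
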