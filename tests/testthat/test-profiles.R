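test_that("body bins tile the transcript exactly and are disjoint", {
  set.seed(7)
  for (k in 1:1000) {
    L <- sample(20:5000, 1)
    s <- sample(6000:20000, 1)
    g <- make_gene(s, s + L, sample(c("+", "-"), 1))
    bins <- gene_bins(g[1, ])
    body <- bins[bins$section == "body", ]
    body <- body[order(body$start), ]
    expect_equal(body$start[1], s)
    expect_equal(body$end[nrow(body)], s + L)
    expect_true(all(body$start[-1] == body$end[-nrow(body)]))
    expect_true(all(abs(diff(body$end - body$start)) <= 1))
  }
})

test_that("worked bin-index examples hold", {
  g <- make_gene(0L, 2000L, "+")
  # probe midpoint 150 -> body bin index 1 (0-based), 100 bp bins
  expect_equal(impl_slot(150L, g[1, ]), 10L + 1L + 1L)  # 1-based slot 12
  gm <- make_gene(0L, 2000L, "-")
  # same midpoint on minus strand -> body bin 18 (0-based)
  expect_equal(impl_slot(150L, gm[1, ]), 10L + 18L + 1L)
  gp <- make_gene(10000L, 30000L, "+")
  # midpoint 3000 bp upstream of TSS: window [5000,10000), 500 bp bins
  expect_equal(impl_slot(7000L, gp[1, ]), 4L + 1L)
})

test_that("bin assignment equals the per-base closed-form lookup", {
  set.seed(17)
  for (k in 1:60) {
    L <- sample(20:8000, 1)
    s <- sample(6000:30000, 1)
    strand <- sample(c("+", "-"), 1)
    g <- make_gene(s, s + L, strand)
    mids <- sample((s - 6000):(s + L + 6000), 300, replace = TRUE)
    expect_equal(impl_slot(mids, g[1, ]),
                 oracle_slot(mids, s, s + L, strand))
  }
})

test_that("bin_gene_profile averages probes per bin and reverses on minus", {
  set.seed(23)
  s <- 20000L; L <- 4321L
  starts <- sort(sample(seq(s - 6000L, s + L + 6000L, by = 37L), 400))
  vals <- rnorm(400)
  tr <- make_track(starts, vals, width = 50L)
  gp <- make_gene(s, s + L, "+")
  gn <- make_gene(s, s + L, "-")
  pp <- bin_gene_profile(gp[1, ], tr)
  pn <- bin_gene_profile(gn[1, ], tr)
  expect_length(pp$bins, 40)
  # strand reversal flips the vector exactly
  expect_equal(pn$bins, rev(pp$bins))
  expect_equal(pn$n_probes, rev(pp$n_probes))
  # oracle recomputation of every bin mean
  mids <- (starts + starts + 50L) %/% 2L
  slots <- oracle_slot(mids, s, s + L, "+")
  for (sl in 1:40) {
    v <- vals[which(slots == sl)]
    if (length(v)) expect_equal(pp$bins[sl], mean(v))
    else expect_true(is.na(pp$bins[sl]))
    expect_equal(pp$n_probes[sl], length(v))
  }
  expect_error(bin_gene_profile(make_gene(0L, 15L)[1, ], tr), "shorter")
})

test_that("all-missing profiles are valid and never zero-filled", {
  tr <- make_track(c(100L, 200L), c(1, 2))
  g <- make_gene(500000L, 510000L)
  p <- bin_gene_profile(g[1, ], tr)
  expect_true(all(is.na(p$bins)))
  expect_true(all(p$n_probes == 0))
})

test_that("composite profiles average only defined bins", {
  p1 <- structure(list(gene_id = "A", mark = "M", condition = "C",
                       bins = c(1, NA, 2), n_probes = c(1L, 0L, 1L)),
                  class = "bin_profile")
  p2 <- structure(list(gene_id = "B", mark = "M", condition = "C",
                       bins = c(3, 5, NA), n_probes = c(1L, 2L, 0L)),
                  class = "bin_profile")
  cp <- composite_profile(list(p1, p2))
  expect_equal(cp$mean, c(2, 5, 2))
  expect_equal(cp$n, c(2, 1, 1))
  solo <- composite_profile(list(p1))
  expect_equal(solo$mean, p1$bins)
  expect_error(composite_profile(list(p1, p2), group = "ZZZ"),
               "empty group")
  p3 <- p2; p3$mark <- "OTHER"
  expect_error(composite_profile(list(p1, p3)), "mix")
})

test_that("composite of a group equals weighted merge over a partition", {
  set.seed(41)
  cfg <- synthetic_config(n_genes = 24, seed = 11)
  b <- simulate_bundle(cfg, sequence = FALSE)
  m <- bin_profile_matrix(b$genes, b$tracks$WT$MIRA)
  ids <- rownames(m$values)
  half <- list(ids[1:10], ids[11:24])
  full <- composite_profile(m)
  parts <- lapply(half, function(grp) composite_profile(m, group = grp))
  merged_n <- parts[[1]]$n + parts[[2]]$n
  num <- ifelse(parts[[1]]$n > 0, parts[[1]]$mean * parts[[1]]$n, 0) +
    ifelse(parts[[2]]$n > 0, parts[[2]]$mean * parts[[2]]$n, 0)
  merged <- ifelse(merged_n > 0, num / merged_n, NA_real_)
  expect_equal(full$n, merged_n)
  expect_equal(full$mean, merged)
})

test_that("clustering is deterministic and keeps identical rows adjacent", {
  set.seed(51)
  base <- matrix(rnorm(40), 1)
  vals <- rbind(base, base, base + 40)
  rownames(vals) <- c("gA", "gB", "gC")
  mats <- list(list(values = vals, n = (vals * 0) + 1L,
                    mark = "M", condition = "C"))
  cm <- cluster_profile_matrix(mats)
  pos <- match(c("gA", "gB"), cm$order)
  expect_equal(abs(diff(pos)), 1)
  # permuting input rows leaves leaf order unchanged
  mats2 <- list(list(values = vals[c(3, 1, 2), ], n = (vals * 0) + 1L,
                     mark = "M", condition = "C"))
  expect_equal(cluster_profile_matrix(mats2)$order, cm$order)
  # row order is a permutation of the input genes
  expect_setequal(cm$order, rownames(vals))
})

test_that("planted clusters are recovered exactly at low noise", {
  skip_if_not_installed("mclust")
  set.seed(61)
  n_per <- 30
  centers <- rbind(c(rep(4, 20), rep(0, 20)),
                   c(rep(0, 20), rep(4, 20)),
                   c(rep(-4, 10), rep(4, 10), rep(-4, 10), rep(4, 10)))
  vals <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rep(centers[k, ], n_per), n_per, byrow = TRUE) +
      matrix(rnorm(n_per * 40, 0, 0.3), n_per)
  }))
  rownames(vals) <- sprintf("g%03d", seq_len(3 * n_per))
  planted <- rep(1:3, each = n_per)
  names(planted) <- rownames(vals)
  cm <- cluster_profile_matrix(list(list(values = vals, n = vals * 0 + 1L,
                                         mark = "M", condition = "C")))
  got <- cutree(cm$hclust, k = 3)
  ari <- mclust::adjustedRandIndex(got, planted[names(got)])
  expect_equal(ari, 1.0)
})

test_that("all-missing rows are dropped with a warning before clustering", {
  vals <- rbind(g1 = rnorm(6), g2 = rnorm(6), g3 = NA_real_ * 1:6)
  mats <- list(list(values = vals, n = vals * 0 + 1L, mark = "M",
                    condition = "C"))
  expect_warning(cm <- cluster_profile_matrix(mats), "dropped")
  expect_setequal(cm$order, c("g1", "g2"))
})

test_that("display scaling centers and saturates without touching stats", {
  m <- matrix(c(-5, 0, 1, 5), 2)
  s <- scale_profile_display(m, center = 1, saturate = 2)
  expect_equal(s, matrix(c(-2, -1, 0, 2), 2))
})
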