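small_phospho <- function(noise_sd = 0, frac = 0.2, blunting = 0.2,
                          n_sites = 500, seed = 9) {
  sim_phospho(phospho_sim_params(n_sites = n_sites, n_proteins = 180,
                                 frac_responsive = frac,
                                 mean_log2_effect = 1, blunting = blunting,
                                 noise_sd = noise_sd, seed = seed))
}

test_that("phospho tables are validated against their design", {
  sp <- small_phospho(n_sites = 20)
  pt <- phospho_table(sp$table, sp$design)
  expect_s3_class(pt, "phospho_table")
  bad <- sp$table
  bad$C03[5] <- -1
  expect_error(phospho_table(bad, sp$design), class = "hsdquant_param_error")
  expect_error(phospho_table(sp$table[, -1], sp$design),
               class = "hsdquant_param_error")
  # dropping two replicates of one condition violates the >= 2 rule
  expect_error(phospho_table(sp$table, sp$design[-(1:2), ]),
               class = "hsdquant_param_error")
})

test_that("channel normalization equalizes totals and preserves ratios", {
  sp <- small_phospho(n_sites = 50, noise_sd = 0.3)
  pt <- phospho_table(sp$table, sp$design)
  nt <- normalize_channels(pt)
  totals <- vapply(nt$design$channel, function(k) sum(nt$table[[k]]),
                   numeric(1))
  expect_lt(diff(range(totals)) / mean(totals), 1e-9)
  # within-channel ratios preserved exactly
  expect_equal(nt$table$C01 / nt$table$C01[1],
               pt$table$C01 / pt$table$C01[1], tolerance = 1e-12)
  # idempotent
  nt2 <- normalize_channels(nt)
  expect_equal(nt2$table, nt$table, tolerance = 1e-12)
  # already equal-total input is unchanged
  tab <- data.frame(site_id = c("s1", "s2"), protein_id = c("p1", "p1"),
                    C1 = c(1, 3), C2 = c(3, 1), C3 = c(2, 2), C4 = c(2, 2))
  des <- data.frame(channel = paste0("C", 1:4), genotype = "g",
                    treatment = rep(c("mock", "insulin"), each = 2),
                    replicate = c(1, 2, 1, 2))
  expect_equal(normalize_channels(phospho_table(tab, des))$table, tab)
})

test_that("per-site ANOVA is calibrated on null sites and powered on shifts", {
  sp <- small_phospho(n_sites = 1000, frac = 0, noise_sd = 0.2, seed = 3)
  pt <- phospho_table(sp$table, sp$design)
  p <- site_anova(pt)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  # planted 2-fold shift in one condition, low noise
  sp2 <- small_phospho(n_sites = 50, frac = 1, noise_sd = 0.05, seed = 4)
  p2 <- site_anova(phospho_table(sp2$table, sp2$design))
  expect_true(all(p2 < 0.01))
  # degenerate flat site: p = 1 by convention
  tab <- data.frame(site_id = "s1", protein_id = "p1",
                    C1 = 4, C2 = 4, C3 = 4, C4 = 4)
  des <- data.frame(channel = paste0("C", 1:4), genotype = "g",
                    treatment = rep(c("mock", "insulin"), each = 2),
                    replicate = c(1, 2, 1, 2))
  expect_equal(unname(site_anova(phospho_table(tab, des))), 1)
})

test_that("response direction respects the 30% threshold on both scales", {
  mk <- function(fc) {
    tab <- data.frame(site_id = "s1", protein_id = "p1",
                      C1 = 100, C2 = 100, C3 = 100 * fc, C4 = 100 * fc)
    des <- data.frame(channel = paste0("C", 1:4), genotype = "g",
                      treatment = rep(c("mock", "insulin"), each = 2),
                      replicate = c(1, 2, 1, 2))
    phospho_table(tab, des)
  }
  # single-site fixture: skip channel normalization, which would by
  # construction equalize the only abundance in every channel
  dir_at <- function(fc, ...)
    insulin_response(mk(fc), "g", normalize = FALSE, ...)$direction
  expect_equal(dir_at(1.31), "up")
  expect_equal(dir_at(1.30), "up") # boundary: >= 1 + theta
  expect_equal(dir_at(1.29), "none")
  expect_equal(dir_at(1 / 1.30), "down") # reciprocal rule (default)
  expect_equal(dir_at(0.78), "none")
  expect_equal(dir_at(0.72, down_rule = "raw"), "none")
  expect_equal(dir_at(0.69, down_rule = "raw"), "down")
  expect_error(insulin_response(mk(1), "absent"),
               class = "hsdquant_param_error")
})

test_that("noiseless planted responses are recovered exactly", {
  sp <- small_phospho(noise_sd = 0)
  pt <- phospho_table(sp$table, sp$design)
  r <- insulin_response(pt, "control")
  cc <- count_changes(r)
  expect_setequal(cc$up_sites,
                  sp$truth$site_id[sp$truth$direction == "up"])
  expect_setequal(cc$down_sites,
                  sp$truth$site_id[sp$truth$direction == "down"])
  expect_equal(cc$n_total, cc$n_up + cc$n_down)
  expect_length(intersect(cc$up_sites, cc$down_sites), 0)
})

test_that("null simulations produce few calls, fewer with less noise", {
  counts <- vapply(c(0.02, 0.15), function(ns) {
    sp <- small_phospho(noise_sd = ns, frac = 0, seed = 11)
    cc <- count_changes(insulin_response(
      phospho_table(sp$table, sp$design), "control"))
    cc$n_total
  }, numeric(1))
  expect_lte(counts[1], counts[2])
  expect_lt(counts[2] / 500, 0.25) # false positives only
})

test_that("blunted knockdowns recover the planted response structure", {
  sp <- sim_phospho(phospho_sim_params(n_sites = 5000, n_proteins = 1500,
                                       frac_responsive = 0.2,
                                       mean_log2_effect = 1, blunting = 0.2,
                                       noise_sd = 0.1, seed = 4))
  pt <- phospho_table(sp$table, sp$design)
  cc <- count_changes(insulin_response(pt, "control"))
  ck1 <- count_changes(insulin_response(pt, "KD1"))
  ck2 <- count_changes(insulin_response(pt, "KD2"))
  expect_lt(abs(cc$n_total - 1000), 100) # planted 0.2 * 5000 within 10%
  expect_lt(ck1$n_total, 0.5 * cc$n_total)
  expect_lt(ck2$n_total, 0.5 * cc$n_total)
})

test_that("fully blunted noiseless knockdowns depend for the whole response", {
  sp <- small_phospho(noise_sd = 0, blunting = 0)
  pt <- phospho_table(sp$table, sp$design)
  rc <- insulin_response(pt, "control")
  dep <- dependent_set(rc, list(insulin_response(pt, "KD1"),
                                insulin_response(pt, "KD2")))
  expect_setequal(dep$sites, sp$truth$site_id)
  expect_equal(dep$fraction_pct, 100)
  # knockdowns identical to control: empty dependence set
  dep0 <- dependent_set(rc, list(rc, rc))
  expect_equal(dep0$n, 0)
  expect_equal(dep0$fraction_pct, 0)
  # mismatched universes rejected
  expect_error(dependent_set(rc, list(rc[-1, ])),
               class = "hsdquant_param_error")
})

test_that("dependence set is contained in the control response and modes nest", {
  sp <- small_phospho(noise_sd = 0.15, blunting = 0.3, seed = 12)
  pt <- phospho_table(sp$table, sp$design)
  rc <- insulin_response(pt, "control")
  kds <- list(insulin_response(pt, "KD1"), insulin_response(pt, "KD2"))
  dall <- dependent_set(rc, kds, mode = "all")
  dany <- dependent_set(rc, kds, mode = "any")
  reg <- rc$site_id[rc$direction != "none"]
  expect_true(all(dall$sites %in% reg))
  expect_true(all(dall$sites %in% dany$sites))
  expect_true(dall$fraction_pct >= 0 && dall$fraction_pct <= 100)
  expect_equal(dall$n, dall$n_up + dall$n_down)
})

test_that("protein dedup matches a brute-force unique count", {
  sp <- small_phospho(n_sites = 200)
  map <- sp$table[, c("site_id", "protein_id")]
  set.seed(2)
  for (i in 1:10) {
    sites <- sample(map$site_id, sample(1:100, 1))
    expect_setequal(dedupe_proteins(sites, map),
                    unique(map$protein_id[map$site_id %in% sites]))
  }
  expect_equal(dedupe_proteins(character(0), map), character(0))
  expect_equal(dedupe_proteins(rep(map$site_id[1], 3), map),
               map$protein_id[1]) # 3 sites on one protein -> 1 protein
  expect_error(dedupe_proteins("nope", map), class = "hsdquant_param_error")
})

test_that("venn regions match exhaustive membership enumeration", {
  v <- venn_overlap(list(A = "a", B = "b"))
  expect_equal(v$count[v$region == "A"], 1L)
  expect_equal(v$count[v$region == "B"], 1L)
  expect_equal(v$count[v$region == "A&B"], 0L)
  ident <- venn_overlap(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(ident$count[ident$region == "A&B"], 2L)
  expect_equal(sum(ident$count), 2L)
  set.seed(31)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) sample(letters, sample(5:20, 1)))
    names(sets) <- c("A", "B", "C")
    v <- venn_overlap(sets)
    expect_equal(sum(v$count), length(unique(unlist(sets))))
    # spot-check each element lands in exactly one region
    for (el in unique(unlist(sets))) {
      memb <- vapply(sets, function(s) el %in% s, logical(1))
      row <- v[v$A == memb[1] & v$B == memb[2] & v$C == memb[3], ]
      expect_equal(nrow(row), 1L)
    }
  }
})

test_that("pathway overrepresentation matches the hypergeometric oracle", {
  bg <- sprintf("g%02d", 1:8)
  hits <- bg[1:4]
  # 2x2 table (3, 1, 1, 3)
  res <- enrichment(hits, bg, list(P = c(bg[1:3], bg[5])))
  expect_equal(res$p, fisher_oracle(3, 1, 1, 3), tolerance = 1e-12)
  expect_equal(res$p, 0.485714285714, tolerance = 1e-9)
  # hits = background: no enrichment possible
  res2 <- enrichment(bg, bg, list(P = bg[1:3]))
  expect_equal(res2$p, 1)
  # disjoint pathway skipped with warning
  expect_warning(res3 <- enrichment(hits, bg, list(Q = c("zz", "yy"))),
                 "skipped")
  expect_equal(nrow(res3), 0L)
  expect_error(enrichment(c(hits, "not_bg"), bg, list(P = bg[1:2])),
               class = "hsdquant_param_error")
  expect_error(enrichment(hits, character(0), list(P = bg[1:2])),
               class = "hsdquant_param_error")
})
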