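test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(tissue = list(effect = 1.2)), "effect")
  expect_error(sim_params(tissue = list(n_control = 0)), "group sizes")
  expect_error(sim_params(qmsp = list(cp_slope = 0)), "cp_slope")
  expect_error(sim_params(tissue = list(read_depth = -1)), "read_depth")
  expect_error(sim_params(n_genes = 15), "too small")
  expect_s3_class(sim_params(tissue = list(effect = 0)), "sim_params")
})

test_that("every generator is deterministic under a fixed seed", {
  p <- sim_params(n_genes = 60, seed = 61)
  expect_identical(generate_tissue_readset(p), generate_tissue_readset(p))
  expect_identical(generate_array_dataset(p), generate_array_dataset(p))
  expect_identical(generate_array_dataset(p, "pooled"),
                   generate_array_dataset(p, "pooled"))
  expect_identical(generate_qmsp_cohort(p), generate_qmsp_cohort(p))
  p2 <- sim_params(n_genes = 60, seed = 62)
  expect_false(identical(generate_tissue_readset(p)$reads,
                         generate_tissue_readset(p2)$reads))
})

test_that("null tissue simulator shows no case/control count difference", {
  p <- sim_params(n_genes = 60, seed = 63, latent_sd = 0,
                  tissue = list(effect = 0, n_case = 20, n_control = 20))
  tis <- generate_tissue_readset(p)
  w <- make_tss_windows(tis$annotation)
  wm <- quantify_windows(tis$reads, w, tis$totals)
  pos <- tis$labels == "OC"
  diff <- rowMeans(wm$levels[, pos]) - rowMeans(wm$levels[, !pos])
  # per-gene mean fraction ~ 1e-5 * base_meth; differences are pure noise
  expect_lt(abs(mean(diff)), 2e-7)
})

test_that("marker window counts scale with latent methylation (Monte-Carlo)", {
  # base 0.4 plus effect 0.2 -> analytic case/control mean ratio 1.5
  ratios <- vapply(1:40, function(s) {
    p <- sim_params(
      n_genes = 20, n_markers = 2, n_sex_genes = 2, n_non_nm = 2,
      seed = 700 + s, base_meth_range = c(0.4, 0.4), latent_sd = 0,
      tissue = list(effect = 0.2, n_case = 5, n_control = 5)
    )
    tis <- generate_tissue_readset(p)
    w <- make_tss_windows(tis$annotation)
    wm <- quantify_windows(tis$reads, w, tis$totals)
    g <- tis$truth$marker_genes[1]
    mean(wm$levels[g, tis$labels == "OC"]) / mean(wm$levels[g, tis$labels == "normal"])
  }, numeric(1))
  # Poisson error at depth 1e6 x 5e-5 x 0.4 = 20 reads/window, 200 windows
  expect_equal(mean(ratios), 1.5, tolerance = 0.05)
})

test_that("array generator plants the promised probe-level beta shift", {
  diffs <- vapply(1:20, function(s) {
    p <- sim_params(n_genes = 30, seed = 800 + s,
                    array = list(effect = 0.2, n_case = 10, n_control = 10))
    arr <- generate_array_dataset(p)
    g <- arr$truth$marker_genes[1]
    pr <- arr$probes$probe_id[arr$probes$closest_gene == g]
    pos <- arr$labels == "OC"
    mean(arr$betas[pr, pos]) - mean(arr$betas[pr, !pos])
  }, numeric(1))
  expect_equal(mean(diffs), 0.2, tolerance = 0.02)

  # manifest covers exactly the genes of the universe, >= min probes each
  p <- sim_params(n_genes = 20, n_markers = 3, n_sex_genes = 2, n_non_nm = 2,
                  seed = 64)
  arr <- generate_array_dataset(p)
  tab <- table(arr$probes$closest_gene)
  expect_equal(length(tab), 20L)
  expect_true(all(tab >= p$probes_per_gene$min))
  expect_true(all(arr$betas >= 0 & arr$betas <= 1))
})

test_that("with no SNPs and no detection failures QC removes only annotation decoys", {
  p <- sim_params(n_genes = 40, seed = 65, snp_frac = 0, detp_fail_frac = 0)
  arr <- generate_array_dataset(p)
  qc <- qc_filter_probes(arr$probes, arr$betas, arr$detection_p)
  removed <- setdiff(arr$probes$probe_id, qc$probes$probe_id)
  removed_info <- arr$probes[arr$probes$probe_id %in% removed, ]
  expect_true(all(
    removed_info$chrom %in% c("chrX", "chrY") |
      !startsWith(removed_info$accession, "NM_")
  ))
})

test_that("pooled betas equal equal-mass averages of their specimens' latents", {
  p <- sim_params(n_genes = 20, n_markers = 3, n_sex_genes = 2, n_non_nm = 2,
                  seed = 66)
  poo <- generate_array_dataset(p, "pooled")
  expect_equal(ncol(poo$betas),
               p$pooled$n_case_pools + p$pooled$n_control_pools)
  expect_equal(length(unique(poo$truth$pool_membership)), ncol(poo$betas))
  expect_equal(unname(table(poo$truth$pool_membership)[1]), 5L)
})

test_that("qMSP cohorts land on the calibration medians and flag failed references", {
  p <- sim_params(seed = 67)
  tr <- generate_qmsp_cohort(p, set = "training")
  expect_equal(nrow(tr$measurements), (31 + 31) * 3 * 2)
  d <- delta_cp_matrix(tr$measurements)
  med_oc <- median(d$delta_cp[d$labels == "OC", "TBX15"], na.rm = TRUE)
  med_n <- median(d$delta_cp[d$labels == "normal", "TBX15"], na.rm = TRUE)
  # published training medians 5.1 / 7.6; sampling noise at n = 31
  expect_equal(med_oc, 5.1, tolerance = 0.8)
  expect_equal(med_n, 7.6, tolerance = 0.8)

  # noiseless null: case and control delta-Cp identical per gene
  p0 <- sim_params(seed = 68, latent_sd = 0,
                   qmsp = list(cp_noise_sd = 0, ref_sd = 0, replicate_sd = 0,
                               ref_fail_frac = 0))
  tm0 <- data.frame(gene = "X", group = c("OC", "normal"), median = 3,
                    stringsAsFactors = FALSE)
  q0 <- generate_qmsp_cohort(p0, gene_panel = "X", target_medians = tm0)
  d0 <- delta_cp_matrix(q0$measurements)
  expect_equal(unname(d0$delta_cp[, "X"]), rep(3, 62), tolerance = 1e-9)

  # reference-failure fraction produces the expected number of flags
  pf <- sim_params(seed = 69, qmsp = list(ref_fail_frac = 0.1,
                                          n_train = c(case = 50, control = 50)))
  flagged <- vapply(1:20, function(s) {
    pf$seed <- 69 + s
    length(generate_qmsp_cohort(pf, set = "training")$truth$ref_failed_samples)
  }, numeric(1))
  expect_equal(mean(flagged), 10, tolerance = 2) # binomial(100, 0.1)
})

test_that("realized group medians track externally supplied targets", {
  errs <- vapply(1:25, function(s) {
    p <- sim_params(seed = 900 + s)
    te <- generate_qmsp_cohort(p, set = "testing")
    d <- delta_cp_matrix(te$measurements)
    tm <- te$truth$target_medians
    max(vapply(seq_len(nrow(tm)), function(i) {
      grp <- d$labels == tm$group[i]
      abs(median(d$delta_cp[grp, tm$gene[i]], na.rm = TRUE) - tm$median[i])
    }, numeric(1)))
  }, numeric(1))
  # n = 21 per group: median realized within ~0.3 cycles of target
  expect_lte(median(errs), 0.75)
  expect_lte(mean(errs <= 1.2), 1)
})
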