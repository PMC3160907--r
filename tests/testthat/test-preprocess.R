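# internal-standard normalization and pre-model standardization

test_that("every lipid class dispatches to its printed standard", {
  m <- default_standard_map()
  cases <- list(
    # monoacyl lipids except cholesteryl esters -> lysoPC standard
    c("LysoPC(16:1)", "PC(17:0/0:0)"),
    c("LysoPE(18:0)", "PC(17:0/0:0)"),
    c("PC(17:0/0:0)", "PC(17:0/0:0)"),
    # diacyl lipids except ethanolamine phospholipids -> diacyl PC standard
    c("PC(36:5)", "PC(17:0/17:0)"),
    c("PC(34:4e)", "PC(17:0/17:0)"),
    c("SM(d18:1/22:0)", "PC(17:0/17:0)"),
    # ceramides
    c("Cer(d18:1/24:0)", "Cer(d18:1/17:0)"),
    # diacyl (and ether/plasmalogen) ethanolamine phospholipids
    c("PE(36:4)", "PE(17:0/17:0)"),
    c("PE(P-16:0/20:5)", "PE(17:0/17:0)"),
    # TG and sterol esters
    c("TG(54:3)", "TG(17:0/17:0/17:0)"),
    c("ChoE(18:2)", "TG(17:0/17:0/17:0)"),
    c("FCho", "TG(17:0/17:0/17:0)")
  )
  for (cs in cases) {
    expect_equal(assign_standard(cs[1], m), cs[2], label = cs[1])
  }
})

test_that("standard assignment is exhaustive over the class enum", {
  m <- default_standard_map()
  examples <- c(PC = "PC(34:2)", lysoPC = "LysoPC(18:1)", PE = "PE(38:4)",
                lysoPE = "LysoPE(18:0)", PE_plasmalogen = "PE(P-18:0/20:4)",
                PC_ether = "PC(36:4e)", SM = "SM(d18:1/16:0)",
                Cer = "Cer(d18:1/16:0)", TG = "TG(52:2)", ChoE = "ChoE(20:5)",
                FCho = "FCho")
  for (cls in setdiff(lipid_classes(), "unknown")) {
    p <- parse_lipid_name(examples[[cls]])
    expect_equal(p$lipid_class, cls)
    expect_true(assign_standard(p, m) %in% m$standards$standard_id,
                label = cls)
  }
})

test_that("unknown peaks dispatch by retention time with exact boundaries", {
  m <- default_standard_map()
  expect_equal(assign_standard("pk", m, retention_time = 250), "PC(17:0/0:0)")
  expect_equal(assign_standard("pk", m, retention_time = 0), "PC(17:0/0:0)")
  expect_equal(assign_standard("pk", m, retention_time = 299.999),
               "PC(17:0/0:0)")
  expect_equal(assign_standard("pk", m, retention_time = 300),
               "PC(17:0/17:0)")
  expect_equal(assign_standard("pk", m, retention_time = 410),
               "PC(17:0/17:0)")
  expect_equal(assign_standard("pk", m, retention_time = 410.001),
               "TG(17:0/17:0/17:0)")
  expect_equal(assign_standard("pk", m, retention_time = 800),
               "TG(17:0/17:0/17:0)")
  expect_error(assign_standard("pk", m), "no retention time")
})

test_that("normalization applies divide-by-standard-times-concentration exactly", {
  # constructed intensities: lipid 500 vs standard 1000 at concentration 0.75
  vals <- rbind(
    `PC(36:5)` = c(500, 250),
    `PC(17:0/17:0)` = c(1000, 500),
    `PC(17:0/0:0)` = c(800, 400),
    `Cer(d18:1/17:0)` = c(100, 50),
    `PE(17:0/17:0)` = c(200, 100),
    `TG(17:0/17:0/17:0)` = c(400, 200),
    `LysoPC(18:1)` = c(800, 800)
  )
  tab <- peak_table(vals, peak_ids = rownames(vals), sample_ids = c("s1", "s2"),
                    names = rownames(vals), unit = "raw_intensity")
  m <- default_standard_map(concentrations = c("PC(17:0/17:0)" = 0.75))
  out <- normalize_peaks(tab, m)
  expect_equal(out$unit, "concentration")
  # standard rows dropped
  expect_setequal(out$peaks$peak_id, c("PC(36:5)", "LysoPC(18:1)"))
  expect_identical(out$values["PC(36:5)", "s1"], 500 / 1000 * 0.75)
  expect_identical(out$values["PC(36:5)", "s1"], 0.375)
  # lipid intensity equal to its standard's -> concentration = standard's
  expect_identical(out$values["LysoPC(18:1)", "s1"], 1.0)
  # ratio 500/1000 is preserved in the second sample (250/500)
  expect_identical(out$values["PC(36:5)", "s2"], 0.375)
})

test_that("normalized concentrations are invariant to per-sample scaling", {
  st <- generate_study(generator_config_small(n_lipids = 20, n_identified = 14,
                                              n_clusters = 2,
                                              n_patients = c(2, 2, 2),
                                              seed = 9))
  raw <- as_raw_intensities(st$table, seed = 4)
  out1 <- normalize_peaks(raw)
  # double every intensity of sample 3: concentrations unchanged bit-exactly
  raw2 <- raw
  raw2$values[, 3] <- raw2$values[, 3] * 2
  out2 <- normalize_peaks(raw2)
  expect_identical(out1$values, out2$values)
  # and the raw-intensity view inverts to the generated concentrations
  expect_equal(out1$values, st$table$values, tolerance = 1e-12)
})

test_that("normalization commutes with row and column reordering", {
  st <- generate_study(generator_config_small(n_lipids = 15, n_identified = 10,
                                              n_clusters = 2,
                                              n_patients = c(2, 2, 2),
                                              seed = 3))
  raw <- as_raw_intensities(st$table, seed = 2)
  out <- normalize_peaks(raw)
  perm_r <- rev(seq_len(nrow(raw$values)))
  perm_c <- rev(seq_len(ncol(raw$values)))
  raw_perm <- peak_table(raw$values[perm_r, perm_c],
                         peak_ids = raw$peaks$peak_id[perm_r],
                         sample_ids = raw$sample_ids[perm_c],
                         names = raw$peaks$name[perm_r],
                         retention_time = raw$peaks$retention_time[perm_r],
                         unit = "raw_intensity")
  out_perm <- normalize_peaks(raw_perm)
  expect_identical(out_perm$values[rownames(out$values), colnames(out$values)],
                   out$values)
})

test_that("nonpositive standard intensities are rejected with names", {
  vals <- rbind(`PC(36:5)` = c(500, 250), `PC(17:0/17:0)` = c(1000, 0),
                `PC(17:0/0:0)` = c(1, 1), `Cer(d18:1/17:0)` = c(1, 1),
                `PE(17:0/17:0)` = c(1, 1), `TG(17:0/17:0/17:0)` = c(1, 1))
  tab <- peak_table(vals, rownames(vals), c("s1", "s2"), names = rownames(vals),
                    unit = "raw_intensity")
  expect_error(normalize_peaks(tab), "PC\\(17:0/17:0\\).*nonpositive.*s2")
})

test_that("a standard map round trips through YAML config", {
  m <- default_standard_map(concentrations = c("Cer(d18:1/17:0)" = 0.6))
  path <- withr::local_tempfile(fileext = ".yaml")
  std <- lapply(seq_len(nrow(m$standards)), function(i) {
    list(standard_id = m$standards$standard_id[i],
         concentration = m$standards$concentration[i])
  })
  names(std) <- m$standards$rule
  rt <- lapply(seq_len(nrow(m$rt_rules)), function(i) {
    list(rt_upper = m$rt_rules$rt_upper[i],
         standard_id = m$rt_rules$standard_id[i],
         inclusive = m$rt_rules$inclusive[i])
  })
  yaml::write_yaml(list(standards = std, rt_rules = rt), path)
  m2 <- read_standard_map(path)
  expect_equal(m2$standards[order(m2$standards$rule), ],
               m$standards[order(m$standards$rule), ],
               ignore_attr = TRUE)
  expect_equal(m2$rt_rules$rt_upper, m$rt_rules$rt_upper)
})

test_that("standardization gives mean 0 / sd 1 and inverts exactly", {
  set.seed(31)
  tab <- toy_peak_table(8, 10, seed = 31, unit = "concentration")
  sc <- standardize(tab, transform = "z")
  expect_equal(unname(rowMeans(sc$x)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(sc$x, 1, sd)), rep(1, 8), tolerance = 1e-12)
  back <- inverse_transform(sc)
  expect_lt(max(abs(back - tab$values)), 1e-9)

  # log_z round trip on random positive tables
  sc2 <- standardize(tab, transform = "log_z")
  expect_equal(unname(rowMeans(sc2$x)), rep(0, 8), tolerance = 1e-12)
  back2 <- inverse_transform(sc2)
  expect_lt(max(abs(back2 - tab$values)), 1e-9)
})

test_that("constant lipids are excluded with a count, zeros get a pseudo-count", {
  vals <- rbind(a = c(1, 2, 4), b = c(5, 5, 5), c = c(0, 2, 4))
  tab <- peak_table(vals, rownames(vals), c("s1", "s2", "s3"),
                    unit = "concentration")
  expect_warning(sc <- standardize(tab, "log_z"), "1 constant lipid")
  expect_equal(sc$excluded, "b")
  expect_equal(nrow(sc$x), 2)
  # zero in lipid c was replaced by half its smallest positive value (1)
  expect_equal(inverse_transform(sc)["c", 1], 1, tolerance = 1e-12)
})
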