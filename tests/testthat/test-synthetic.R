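test_that("generated libraries follow the WSN x 10 design", {
  bc <- generate_library(1000, off_pattern_rate = 0, seed = 1)
  expect_length(bc, 1000)
  expect_false(anyDuplicated(bc) > 0)
  expect_true(all(nchar(bc) == 30))
  expect_true(all(grepl("^([AT][GC][ACGT]){10}$", bc)))

  one <- generate_library(1, off_pattern_rate = 0, seed = 7)
  expect_equal(nchar(one), 30)
})

test_that("off-pattern fraction is exact under an independent regex check", {
  bc <- generate_library(500, off_pattern_rate = 0.9, seed = 2)
  off <- !grepl("^([AT][GC][ACGT]){10}$", bc)
  expect_equal(sum(off), 450)
  expect_true(all(nchar(bc) == 30))
  expect_false(anyDuplicated(bc) > 0)
})

test_that("library generation is deterministic under a fixed seed and fails beyond capacity", {
  expect_identical(as.character(generate_library(50, 0.2, seed = 9)),
                   as.character(generate_library(50, 0.2, seed = 9)))
  expect_error(generate_library(16^10 + 1), "diversity")
})

test_that("deterministic growth preserves frequencies; single clone stays fixed", {
  st <- clone_state(generate_library(10, 0, seed = 3))
  g <- simulate_growth(st, fold = 1, dispersion = 0)
  expect_equal(g$frequencies, st$frequencies)

  solo <- clone_state("ACGTACGTACGTACGTACGTACGTACGTAC")
  g2 <- simulate_growth(solo, fold = 200, dispersion = 0.1, seed = 1)
  expect_equal(g2$frequencies, 1)
})

test_that("noisy growth cannot raise the expected effective clone number", {
  st <- clone_state(generate_library(1000, 0, seed = 4))
  ecn0 <- corrected_barcode_number(st$frequencies)
  ecn <- vapply(1:100, function(s) {
    corrected_barcode_number(
      simulate_growth(st, fold = 200, dispersion = 0.2, seed = s)$frequencies)
  }, numeric(1))
  expect_true(all(ecn <= ecn0 + 1e-9))
  expect_lt(mean(ecn), ecn0)
})

test_that("bottlenecks cap the surviving support at the founder count", {
  st <- clone_state(generate_library(1000, 0, seed = 5))
  b1 <- simulate_bottleneck(st, founders = 1, seed = 1)
  expect_length(b1$barcodes, 1)
  expect_equal(b1$frequencies, 1)

  b2 <- simulate_bottleneck(st, founders = 2, seed = 2)
  expect_lte(length(b2$barcodes), 2)

  expect_error(simulate_bottleneck(clone_state("A", n_cells = 10), 11),
               "founders")
})

test_that("bottleneck sampling matches the exhaustive without-replacement law at tiny n", {
  # 3 clones with 2 cells each, draw 2 founders: P(both founders same clone)
  # = 3 * C(2,2) / C(6,2) = 0.2
  st <- clone_state(c("AAA", "CCC", "GGG"), n_cells = 6)
  singles <- vapply(1:4000, function(s) {
    length(simulate_bottleneck(st, 2, seed = s)$barcodes) == 1
  }, logical(1))
  expect_equal(mean(singles), 0.2, tolerance = 0.15)
})

test_that("selection thins binomially and never invents barcodes", {
  st <- clone_state(generate_library(100, 0, seed = 6))
  same <- simulate_selection(st, survival = 1)
  expect_identical(same$barcodes, st$barcodes)

  sel <- simulate_selection(st, survival = 0.5, seed = 1)
  expect_true(all(sel$barcodes %in% st$barcodes))
  expect_lt(sel$n_cells, st$n_cells)

  # one fully resistant clone against near-lethal selection dominates
  surv <- c(1, rep(0.001, 99))
  dom <- simulate_selection(st, survival = surv, seed = 2)
  expect_gt(dom$frequencies[dom$barcodes == st$barcodes[1]], 0.9)
})

test_that("recording follows the Poisson editing law and respects expression zero", {
  tpl <- fixture_template()
  st <- clone_state(generate_library(4, 0, seed = 8),
                    expression = c(1, 1, 0, 2), stg_template = tpl)
  none <- simulate_recording(st, gene_rate = 0, days = 14, seed = 1)
  expect_true(all(latent_edited_fraction(none) == 0))

  rec <- simulate_recording(st, gene_rate = log(2), days = 1, seed = 2)
  f <- latent_edited_fraction(rec)
  expect_equal(f[1], 0.5, tolerance = 1e-12)  # rate * expr * days = ln 2
  expect_equal(f[3], 0)                       # expression-zero clone
  expect_equal(f[4], 0.75, tolerance = 1e-12) # 1 - exp(-2 ln 2)
})

test_that("edited fraction is nondecreasing in days and in expression", {
  tpl <- fixture_template()
  for (s in 1:10) {
    st <- clone_state(generate_library(3, 0, seed = s),
                      expression = c(0.2, 1, 3), stg_template = tpl)
    d3 <- latent_edited_fraction(simulate_recording(st, 0.1, 3, seed = s))
    d7 <- latent_edited_fraction(
      simulate_recording(simulate_recording(st, 0.1, 3, seed = s), 0.1, 4,
                         seed = s + 100))
    expect_true(all(d7 >= d3 - 1e-12))
    expect_true(all(diff(d3) >= -1e-12))  # monotone in expression
  }
})

test_that("disrupted cut windows are never re-edited", {
  tpl <- fixture_template()
  st <- clone_state("ACGTACGTACGTACGTACGTACGTACGTAC", expression = 10,
                    stg_template = tpl)
  rec <- simulate_recording(st, gene_rate = 5, days = 10, seed = 3)
  pool1 <- rec$stg_pool[[1]]
  # template mass is almost exhausted; re-record and check edited variants
  # keep their identity (no second-generation edits of disrupted molecules)
  rec2 <- simulate_recording(rec, gene_rate = 5, days = 10, seed = 4)
  pool2 <- rec2$stg_pool[[1]]
  edited1 <- setdiff(names(pool1), tpl)
  expect_true(all(edited1 %in% names(pool2)))
  for (v in edited1) expect_gte(pool2[[v]], pool1[[v]] - 1e-12)
})

test_that("error-free emission is exact, parseable and byte-deterministic", {
  st <- clone_state("ACGTACGTACGTACGTACGTACGTACGTAC")
  fq <- emit_fastq(st, 100, error_model(), layout = "tumor", seed = 1)
  expect_equal(nrow(fq$reads), 100)
  expect_true(all(grepl(st$barcodes, fq$reads$seq, fixed = TRUE)))
  expect_equal(fq$truth$barcode, rep(st$barcodes, 100))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  tpl <- fixture_template()
  st2 <- clone_state(generate_library(5, 0, seed = 2), expression = 1,
                     stg_template = tpl)
  a <- emit_fastq(st2, 200, error_model(0.01, 0.001), "recording", seed = 9,
                  dir = d1, prefix = "s")
  b <- emit_fastq(st2, 200, error_model(0.01, 0.001), "recording", seed = 9,
                  dir = d2, prefix = "s")
  expect_identical(readBin(a$fastq, "raw", file.size(a$fastq)),
                   readBin(b$fastq, "raw", file.size(b$fastq)))
})

test_that("substitution errors hit barcodes at the binomial expectation", {
  st <- clone_state("ACGTACGTACGTACGTACGTACGTACGTAC")
  fq <- emit_fastq(st, 3000, error_model(substitution_rate = 0.01),
                   layout = "tumor", seed = 4)
  pat <- amplicon_pattern("tumor")
  bc_obs <- substr(fq$reads$seq, nchar(pat$upstream_flank) + 1,
                   nchar(pat$upstream_flank) + 30)
  mm <- vapply(bc_obs, function(b) hamming(b, st$barcodes), numeric(1))
  expect_equal(mean(mm), 0.3, tolerance = 0.12)  # 30 * 0.01
})

test_that("recording-layout reads round-trip through extraction", {
  tpl <- fixture_template()
  st <- clone_state(generate_library(8, 0, seed = 11), expression = 2,
                    stg_template = tpl)
  st <- simulate_recording(st, 0.2, 7, seed = 12)
  fq <- emit_fastq(st, 300, error_model(), "recording", seed = 13)
  ex <- extract_reads(fq$reads, amplicon_pattern("recording"))
  expect_true(all(ex$status == "pass"))
  expect_identical(ex$barcode, fq$truth$barcode)
  expect_identical(ex$stg, fq$truth$stg)
})
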