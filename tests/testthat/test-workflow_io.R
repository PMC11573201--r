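test_that("clone tables round-trip through the tab-delimited format", {
  tab <- gen_clone_size_table(synthetic_config(n_clones = 30, days = 8,
                                               seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clone_table(tab, path)
  back <- read_clone_table(path, drop_singletons = FALSE)
  expect_equal(back$n_cells, tab$n_cells)
  expect_equal(back$clone_id, tab$clone_id)
})

test_that("malformed clone tables are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clone_id\treplicate\tcondition\tday\tn_cells",
               "c1\tr1\thp\t8\t12",
               "c2\tr1\thp\t8\t0",
               "c3\tr1\thp\t8\t4"), path)
  expect_error(read_clone_table(path), "line\\(s\\): 2")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clone_id\tday\tn_cells", "c1\t8\t12"), path2)
  expect_error(read_clone_table(path2), "replicate")
})

test_that("the singleton filter is applied at load time and logged", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clone_id\treplicate\tcondition\tday\tn_cells",
               "c1\tr1\thp\t8\t1",
               "c2\tr1\thp\t8\t1",
               "c3\tr1\thp\t8\t4"), path)
  expect_message(tab <- read_clone_table(path), "2 singleton")
  expect_equal(nrow(tab), 1)
  expect_equal(nrow(read_clone_table(path, drop_singletons = FALSE)), 3)
})

test_that("long and wide barcode layouts load identically", {
  long_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("barcode\tsample\treads",
               "b1\tA\t10", "b2\tA\t20", "b3\tA\t30", "b4\tA\t40",
               "b1\tB\t15", "b2\tB\t25", "b3\tB\t35", "b4\tB\t45"),
             long_path)
  wide_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("barcode\tA\tB",
               "b1\t10\t15", "b2\t20\t25", "b3\t30\t35", "b4\t40\t45"),
             wide_path)
  long_tab <- read_barcode_table(long_path, layout = "long")
  wide_tab <- read_barcode_table(wide_path, layout = "wide")
  expect_equal(long_tab$A, wide_tab$A)
  expect_equal(long_tab$B, wide_tab$B)
  expect_equal(long_tab$barcode, wide_tab$barcode)
})

test_that("duplicate rows error and missing combinations become zeros", {
  dup_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("barcode\tsample\treads",
               "b1\tA\t10", "b1\tA\t11"), dup_path)
  expect_error(read_barcode_table(dup_path), "duplicate")
  miss_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("barcode\tsample\treads",
               "b1\tA\t10", "b2\tA\t20", "b1\tB\t5"), miss_path)
  expect_warning(tab <- read_barcode_table(miss_path), "treated as 0")
  expect_equal(tab$B[tab$barcode == "b2"], 0)
})

test_that("spike-in annotations join onto the barcode table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("barcode\tsample\treads",
               "b1\tA\t10", "sp1\tA\t5000"), path)
  sp_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("barcode\ttrue_cells", "sp1\t500"), sp_path)
  tab <- read_barcode_table(path, spikeins = sp_path)
  expect_equal(tab$is_spikein, c(FALSE, TRUE))
  expect_equal(tab$true_cells, c(NA, 500))
})

test_that("the pipeline runs end to end and reproduces byte-identically", {
  cfg <- synthetic_config(n_clones = 100, days = c(5, 8), n_barcodes = 120,
                          seed = 6)
  out1 <- withr::local_tempdir()
  res <- quiet(run_pipeline(cfg, out1, focal_day = 8,
                            g_grid = seq(0.4, 1, by = 0.2),
                            k_grid = seq(0, 0.6, by = 0.2),
                            n_sim_clones = 60, n_null_replicates = 120))
  expected <- c("clones.tsv", "modality.tsv", "barcodes.tsv",
                "heritability.json", "ode_fits.json", "manifest.json")
  expect_true(all(expected %in% list.files(out1)))
  expect_gte(length(res$sweeps), 1)
  expect_true(all(res$clones$n_cells >= 1))
  expect_true(is.finite(res$heritability$empirical_p_r))
  # rerunning the same config reproduces every output byte-for-byte
  out2 <- withr::local_tempdir()
  quiet(run_pipeline(cfg, out2, focal_day = 8,
                     g_grid = seq(0.4, 1, by = 0.2),
                     k_grid = seq(0, 0.6, by = 0.2),
                     n_sim_clones = 60, n_null_replicates = 120))
  for (f in setdiff(expected, "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
  }
})

test_that("pipeline failures on invalid input are clean", {
  cfg <- synthetic_config(n_clones = 50, days = 5, seed = 3)
  out <- withr::local_tempdir()
  expect_error(quiet(run_pipeline(cfg, out, focal_day = 8)),
               "focal_day")
})
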