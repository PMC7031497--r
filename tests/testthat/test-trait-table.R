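test_that("CSV and TSV parse identically, case/order-insensitively", {
  tab <- demo_table()
  csv <- tempfile(fileext = ".csv")
  tsv <- tempfile(fileext = ".tsv")
  write.csv(tab[, c("value", "trait", "species")], csv, row.names = FALSE)
  reord <- tab[, c("value", "trait", "species")]
  names(reord) <- c("VALUE", "Trait", "Species")
  write.table(reord, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  a <- read_trait_table(csv)
  b <- read_trait_table(tsv)
  expect_equal(a$value, b$value)
  expect_equal(a$species, b$species)
  expect_equal(as.vector(attr(a, "group_sizes")), c(6, 6))
})

test_that("malformed tables produce named, located errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("species,trait", "a,sla"), f)
  expect_error(read_trait_table(f), "missing column: value")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("species,trait,value", "a,sla,1.2", "a,sla,oops"), f2)
  expect_error(read_trait_table(f2), "line\\(s\\): 3")
  expect_error(read_trait_table(tempfile()), "file not found")
})

test_that("estimate_traits emits the full factorial per group", {
  tab <- demo_table()[demo_table()$species == "quercus", ]
  res <- estimate_traits(tab, transforms = c("raw", "log"))
  expect_equal(nrow(res), 2 * 8)  # 1 species x 1 trait x 2 transforms x 8
  # identical group under two names -> identical estimates
  tab2 <- demo_table()
  tab2$value[tab2$species == "fagus"] <- tab2$value[tab2$species == "quercus"]
  res2 <- estimate_traits(tab2, estimators = 1:4)
  expect_equal(res2$estimate[res2$species == "fagus"],
               res2$estimate[res2$species == "quercus"])
  # groups below n = 4 are skipped with a warning
  tiny <- rbind(demo_table(), data.frame(species = "x", trait = "sla",
                                         value = c(1, 2, 3)))
  expect_warning(res3 <- estimate_traits(tiny, estimators = 1), "skipping")
  expect_false("x" %in% res3$species)
  expect_error(estimate_traits(demo_table()[0, ]), "empty")
})

test_that("reports round-trip and runs are byte-reproducible", {
  set.seed(3)
  pool <- small_pool(4, 10, 400, 20)
  res <- evaluate_matrix(pool, estimators = c(1, 4), grid = c(10, 20),
                         replicates = 99)
  dir <- file.path(tempfile(), "sub")  # exercises auto-creation
  files <- write_reports(res, paste0(dir, "/run_"),
                         config = list(seed = 3, replicates = 99))
  expect_true(all(file.exists(files)))
  back <- read.csv(file.path(dir, "run_bias.csv"))
  expect_equal(back$mean_cv, res$bias$mean_cv)
  expect_equal(back$pb, res$bias$pb)
  cfg <- yaml::read_yaml(file.path(dir, "run_config.yaml"))
  expect_equal(cfg$seed, 3)
  # same seed, same bytes
  run_once <- function(d) {
    set.seed(3)
    pool <- small_pool(4, 10, 400, 20)
    res <- evaluate_matrix(pool, estimators = c(1, 4), grid = c(10, 20),
                           replicates = 99)
    write_reports(res, paste0(d, "/run_"))
    readLines(file.path(d, "run_bias.csv"))
  }
  expect_identical(run_once(tempfile()), run_once(tempfile()))
})

test_that("the CLI wires subcommands together with proper exit codes", {
  td <- tempfile(); dir.create(td)
  pools_csv <- file.path(td, "pools.csv")
  expect_equal(suppressMessages(itvcv_cli(
    c("simulate", "--pools", "2", "--n-base", "300", "--n-extreme", "15",
      "--seed", "5", "--out", pools_csv))), 0L)
  df <- read.csv(pools_csv)
  expect_equal(nrow(df), 2 * 315)
  expect_true(file.exists(file.path(td, "pools.config.yaml")))

  # estimate on a trait table
  tab_csv <- file.path(td, "tab.csv")
  write.csv(demo_table(), tab_csv, row.names = FALSE)
  out_csv <- file.path(td, "est.csv")
  expect_equal(suppressMessages(itvcv_cli(
    c("estimate", "--input", tab_csv, "--transforms", "raw,log",
      "--out", out_csv))), 0L)
  expect_equal(nrow(read.csv(out_csv)), 2 * 2 * 8)

  # evaluate on the simulated pools
  expect_equal(suppressMessages(itvcv_cli(
    c("evaluate", "--input", pools_csv, "--estimators", "1,4",
      "--grid", "10:20:10", "--replicates", "49", "--seed", "6",
      "--out-prefix", file.path(td, "ev_")))), 0L)
  expect_true(file.exists(file.path(td, "ev_bias.csv")))
  expect_true(file.exists(file.path(td, "ev_run.log")))

  # minsize writes only the kmin table
  expect_equal(suppressMessages(itvcv_cli(
    c("minsize", "--input", pools_csv, "--estimators", "4",
      "--grid", "10:20:10", "--replicates", "49", "--seed", "6",
      "--accuracy", "0.1", "--out-prefix", file.path(td, "ms_")))), 0L)
  expect_true(file.exists(file.path(td, "ms_kmin.csv")))
  expect_false(file.exists(file.path(td, "ms_bias.csv")))

  # user errors -> 1, unknown subcommand -> 1
  expect_equal(suppressMessages(itvcv_cli(c("evaluate", "--input",
    file.path(td, "nope.csv"), "--out-prefix", file.path(td, "x_")))), 1L)
  expect_equal(suppressMessages(itvcv_cli("frobnicate")), 1L)
  expect_equal(suppressMessages(itvcv_cli(
    c("estimate", "--input", tab_csv))), 1L)  # missing --out
  expect_equal(itvcv_cli(character(0)), 0L)   # usage
})
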