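synthetic_record_set <- function() {
  # 2 molecules x 3 functionals x 2 media of fully synthetic records whose
  # gaps/lambdas follow the expected orderings and cis > trans
  funs <- c("B3LYP", "M06", "CAM-B3LYP")
  gap_base <- c(`B3LYP` = 2.1, `M06` = 2.5, `CAM-B3LYP` = 4.5)
  e01_base <- c(`B3LYP` = 2.0, `M06` = 2.1, `CAM-B3LYP` = 2.6)
  recs <- list()
  geoms <- list()
  for (mol in c("cis-toy", "trans-toy")) for (fn in funs) for (md in c("gas", "chloroform")) {
    ctx <- calc_context(fn, "6-31+G(d,p)", md)
    gap <- gap_base[[fn]] + if (mol == "cis-toy") 0.03 else 0
    e01 <- e01_base[[fn]] - if (md == "chloroform") 0.2 else 0
    recs[[length(recs) + 1L]] <- qc_record(
      mol, ctx,
      electronic = electronic_summary(-5.2, -5.2 + gap, context = ctx),
      nlo = gen_nlo_tensors(5 + e01, 100 + gap, 50, seed = 17, context = ctx),
      transitions = list(gen_transition(e01, c(1, 0, 0), 20, context = ctx)))
    bla <- c(`B3LYP` = 0.075, `M06` = 0.079, `CAM-B3LYP` = 0.100)[[fn]]
    p <- gen_polyene(9, 1.36 + bla, 1.36, label = mol, medium = md)
    p$geometry$context <- ctx
    geoms[[length(geoms) + 1L]] <- p
  }
  list(records = recs, geometries = geoms)
}

test_that("build_benchmark populates every derivable cell from the owning module", {
  set <- synthetic_record_set()
  tab <- build_benchmark(set$records, set$geometries)
  expect_s3_class(tab, "benchmark_table")
  expect_equal(nrow(tab), 12L)
  expect_false(anyNA(tab$gap))
  expect_false(anyNA(tab$mu))
  expect_false(anyNA(tab$betavec))
  expect_false(anyNA(tab$lambda01))
  expect_false(anyNA(tab$bla))
  expect_equal(tab$lambda01, 1239.84193 / tab$e01, tolerance = 1e-12)
  prov <- attr(tab, "provenance")
  expect_identical(unique(prov[, "gap"]), "homo_lumo_gap")
  expect_identical(unique(prov[, "bla"]), "compute_bla")
})

test_that("partial records leave the other columns empty, never defaulted", {
  ctx <- calc_context("B3LYP", "6-31G", "gas")
  rec <- qc_record("only-electronic", ctx,
                   electronic = electronic_summary(-5.0, -2.0, context = ctx))
  tab <- build_benchmark(list(rec))
  expect_equal(tab$gap, 3.0)
  expect_true(is.na(tab$mu) && is.na(tab$lambda01) && is.na(tab$bla))
  prov <- attr(tab, "provenance")
  expect_identical(unname(prov[1, "mu"]), "")

  expect_error(build_benchmark(list(rec, rec)), "duplicate")
})

test_that("the reference benchmark equals the packaged tables cell by cell", {
  tab <- reference_benchmark()
  bla <- load_reference_table("bla")
  trn <- load_reference_table("transitions")
  key <- function(d) paste(d$molecule, d$functional, d$medium)
  expect_equal(tab$bla[match(key(bla), key(tab))], bla$bla)
  expect_equal(tab$lambda01[match(key(trn), key(tab))], trn$lambda01)
  expect_equal(tab$mu01_tot[match(key(trn), key(tab))], trn$mu01_tot)
  expect_true(all(attr(tab, "provenance") %in% c("", "fixture")))
  # the erratum row enters with the corrected sign by default
  gap_err <- tab$gap[tab$molecule == "isonorbixin" & tab$functional == "CAM-B3LYP" &
                       tab$medium == "chloroform"]
  expect_equal(gap_err, 4.465)
  lumo_err <- tab$lumo[tab$molecule == "isonorbixin" & tab$functional == "CAM-B3LYP" &
                         tab$medium == "chloroform"]
  expect_equal(lumo_err, -1.911)
})

test_that("the trend suite passes on the reference tables where evaluable", {
  res <- trend_suite(reference_benchmark())
  expect_false(any(res$status == "fail"))
  # electronic coverage is chloroform-only, so gas gap checks are not evaluable
  gap <- res[res$check == "gap_ordering", ]
  expect_equal(sum(gap$status == "pass"), 4L)
  expect_true(all(grepl("gas", gap$key[gap$status == "not_evaluable"])))
  expect_equal(sum(res$check == "bla_ordering" & res$status == "pass"), 8L)
  expect_equal(sum(res$check == "lambda_ordering" & res$status == "pass"), 8L)
  expect_equal(sum(res$check == "solvent_redshift" & res$status == "pass"), 12L)
  expect_equal(sum(res$check == "cis_gt_trans_gap" & res$status == "pass"), 6L)
})

test_that("fault injection flips exactly the affected trend checks", {
  tab <- reference_benchmark()
  res0 <- trend_suite(tab)

  swap <- tab
  i1 <- which(swap$molecule == "bixin" & swap$functional == "B3LYP" & swap$medium == "gas")
  i2 <- which(swap$molecule == "bixin" & swap$functional == "CAM-B3LYP" & swap$medium == "gas")
  swap$bla[c(i1, i2)] <- swap$bla[c(i2, i1)]
  res1 <- trend_suite(swap)
  changed <- which(res0$status != res1$status)
  expect_identical(res1$check[changed], "bla_ordering")
  expect_identical(res1$key[changed], "bixin gas")
  expect_identical(res1$status[changed], "fail")
})

test_that("a constructed cis<trans violation fails only that check", {
  set <- synthetic_record_set()
  tab <- build_benchmark(set$records, set$geometries)
  res0 <- trend_suite(tab, cis_trans_pairs = list(c(cis = "cis-toy", trans = "trans-toy")))
  expect_false(any(res0$status == "fail"))

  # rebuild with the cis gap pushed below the trans gap in one context
  bad <- tab
  i_cis <- which(bad$molecule == "cis-toy" & bad$functional == "M06" & bad$medium == "gas")
  bad$gap[i_cis] <- bad$gap[bad$molecule == "trans-toy" & bad$functional == "M06" &
                              bad$medium == "gas"] - 0.05
  res1 <- trend_suite(bad, cis_trans_pairs = list(c(cis = "cis-toy", trans = "trans-toy")))
  fails <- res1[res1$status == "fail", ]
  expect_equal(nrow(fails), 1L)
  expect_identical(fails$check, "cis_gt_trans_gap")
  expect_match(fails$key, "M06 gas")
})

test_that("re-running the suite on identical inputs is byte-identical", {
  tab <- reference_benchmark()
  expect_identical(trend_suite(tab), trend_suite(tab))
  set <- synthetic_record_set()
  expect_identical(build_benchmark(set$records, set$geometries),
                   build_benchmark(set$records, set$geometries))
})
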