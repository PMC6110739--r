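test_that("a bundle assembles with the documented roles and dictionaries", {
  b <- toy_bundle()
  expect_s3_class(b, "metadata_bundle")
  expect_identical(canonical_name(b$layer1, b$layer1$time_column), "TimeOS")
  expect_identical(canonical_name(b$layer1, b$layer1$event_column), "EventDeath")
  sexmap <- b$layer3[b$layer3$variable == "sex", ]
  expect_setequal(split_tokens(sexmap$tokens[sexmap$code == 1]), c("1", "m", "M"))
  expect_setequal(split_tokens(sexmap$tokens[sexmap$code == 0]), c("0", "f", "F"))
})

test_that("structural invariants are enforced at construction", {
  expect_error(layer1_roles("t", "t"), class = "survmeta_schema_error")
  # a token claimed by two codes of one variable
  expect_error(layer3_map(c("sex", "sex"), c(0L, 1L), c("f|M", "m|M")),
               class = "survmeta_schema_error")
  # duplicate codes
  expect_error(layer3_map(c("sex", "sex"), c(1L, 1L), c("m", "f")),
               class = "survmeta_schema_error")
  # time role must be continuous, event categorical
  expect_error(layer2_specs("t", "nominal", "time"), class = "survmeta_schema_error")
  expect_error(layer2_specs("e", "ratio", "event"), class = "survmeta_schema_error")
  # exactly one time and one event role in layer 2
  expect_error(
    metadata_bundle(layer1_roles("t", "e"),
                    layer2_specs(c("t", "e", "t2"), c("ratio", "nominal", "ratio"),
                                 c("time", "event", "time"))),
    class = "survmeta_schema_error")
})

test_that("measurement scales map onto analysis classes totally", {
  expect_identical(analysis_class(c("nominal", "ordinal", "interval", "ratio")),
                   c("categorical", "categorical", "continuous", "continuous"))
  expect_error(analysis_class("fancy"), class = "survmeta_schema_error")
})

test_that("write/read round trip is the identity and byte-stable", {
  b <- toy_bundle()
  d1 <- withr::local_tempdir()
  write_metadata(b, d1)
  b2 <- read_metadata(file.path(d1, "layer1.csv"), file.path(d1, "layer2.csv"),
                      file.path(d1, "layer3.csv"))
  expect_identical(b2$layer2, b$layer2)
  expect_identical(b2$layer3[order(b2$layer3$variable, b2$layer3$code), ],
                   b$layer3[order(b$layer3$variable, b$layer3$code), ],
                   ignore_attr = TRUE)
  expect_identical(b2$layer1$time_column, b$layer1$time_column)
  expect_identical(b2$layer1$event_column, b$layer1$event_column)
  expect_mapequal(as.list(b2$layer1$extend_columns),
                  as.list(b$layer1$extend_columns))
  # one more pass reproduces the files byte for byte
  d2 <- withr::local_tempdir()
  write_metadata(b2, d2)
  for (f in c("layer1.csv", "layer2.csv", "layer3.csv"))
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
})

test_that("read_metadata rejects missing or malformed layer files", {
  d <- withr::local_tempdir()
  expect_error(read_metadata(file.path(d, "x.csv"), file.path(d, "y.csv"),
                             file.path(d, "z.csv")),
               class = "survmeta_input_error")
  write_metadata(toy_bundle(), d)
  l3 <- utils::read.csv(file.path(d, "layer3.csv"), colClasses = "character")
  l3$code[1] <- "not-a-code"
  utils::write.csv(l3, file.path(d, "layer3.csv"), row.names = FALSE)
  expect_error(read_metadata(file.path(d, "layer1.csv"), file.path(d, "layer2.csv"),
                             file.path(d, "layer3.csv")),
               class = "survmeta_schema_error")
})

test_that("auto-generation follows the distinct-value threshold rule", {
  set.seed(11)
  n <- 200
  tbl <- data.frame(time = rexp(n), status = rbinom(n, 1, 0.5),
                    many = rnorm(n), binary = rbinom(n, 1, 0.4))
  b <- generate_metadata(tbl)
  l2 <- b$layer2
  expect_identical(l2$measurement[l2$name == "many"], "ratio")
  expect_identical(l2$role[l2$name == "time"], "time")
  expect_identical(l2$role[l2$name == "status"], "event")
  expect_identical(l2$measurement[l2$name == "binary"], "nominal")
  expect_setequal(b$layer3$code[b$layer3$variable == "binary"], c(0L, 1L))

  # boundary behaviour checked against the rule as written: categorical iff
  # distinct count <= k
  for (k in c(4L, 6L)) {
    at <- data.frame(time = seq_len(50), status = rep(c(0L, 1L), 25),
                     v = rep(seq_len(k), length.out = 50),
                     w = rep(seq_len(k + 1L), length.out = 50))
    bk <- generate_metadata(at, k = k)
    rule <- function(x) if (length(unique(x)) <= k) "categorical" else "continuous"
    expect_identical(bk$layer2$analysis_class[bk$layer2$name == "v"], rule(at$v))
    expect_identical(bk$layer2$analysis_class[bk$layer2$name == "w"], rule(at$w))
  }

  # overrides win over inference
  b2 <- generate_metadata(tbl, overrides = list(binary = list(measurement = "ratio")))
  expect_identical(b2$layer2$measurement[b2$layer2$name == "binary"], "ratio")
  expect_error(generate_metadata(tbl, overrides = list(nope = list(role = "ignore"))),
               class = "survmeta_input_error")
  expect_error(generate_metadata(tbl[0, ]), class = "survmeta_input_error")
})

test_that("generation is deterministic and always validates its own table", {
  set.seed(42)
  for (r in 1:5) {
    tbl <- random_raw_table()
    b1 <- generate_metadata(tbl)
    b2 <- generate_metadata(tbl)
    expect_identical(b1$layer2, b2$layer2)
    expect_identical(b1$layer3, b2$layer3)
    rep <- validate_metadata(b1, tbl)
    expect_true(rep$is_valid)
  }
})

test_that("validation reports unmapped values and ignorable columns", {
  b <- toy_bundle()
  raw <- toy_raw()
  rep0 <- validate_metadata(b, raw)
  expect_true(rep0$is_valid)

  raw_bad <- raw
  raw_bad$status[1] <- "2"
  rep1 <- validate_metadata(b, raw_bad)
  expect_false(rep1$is_valid)
  expect_true(any(grepl("'2'", rep1$errors$message) &
                  rep1$errors$severity == "error"))

  raw_extra <- cbind(raw, hospital = "A")
  rep2 <- validate_metadata(b, raw_extra)
  expect_true(rep2$is_valid)  # warning only: the column will be ignored
  expect_true(any(rep2$errors$severity == "warning" &
                  grepl("hospital", rep2$errors$message)))
})
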