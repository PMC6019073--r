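test_that("DN name grammar accepts exactly DN + soma letter + two digits", {
  v <- validate_dn_name("DNp01")
  expect_true(v$valid)
  expect_equal(v$soma_group, "p")
  expect_equal(v$index, "01")

  expect_false(validate_dn_name("ANp01")$valid)
  expect_match(validate_dn_name("ANp01")$reason, "prefix")
  expect_false(validate_dn_name("DNg100")$valid)
  expect_match(validate_dn_name("DNg100")$reason, "two digits")

  # exhaustive small-alphabet sweep: every letter x index-width combination
  legal_letters <- c("a", "b", "c", "d", "g", "p", "x")
  for (letter in letters) {
    for (index in c("1", "07", "007", "42", "xx", "")) {
      name <- paste0("DN", letter, index)
      expected <- letter %in% legal_letters && grepl("^[0-9]{2}$", index)
      expect_equal(validate_dn_name(name)$valid, expected, info = name)
    }
  }
})

test_that("default atlases carry the expected compartments and groups", {
  atl <- load_default_atlases()
  expect_true(all(c("IPS", "SPS", "GNG", "PVLP", "AVLP", "PLP", "LAL",
                    "VES", "SMP", "AMMC", "SAD", "WED", "GOR", "EPA",
                    "BU", "AL") %in% atlas_abbrevs(atl$brain)))
  expect_true(all(c("Neck", "Wing", "Haltere", "Tct", "LTct", "LegT1",
                    "LegT2", "LegT3", "AMN", "VAC", "mVAC", "AS") %in%
                    atlas_abbrevs(atl$vnc)))
  expect_equal(unname(atlas_group(atl$vnc, "Wing")), "dorsal")
  expect_equal(unname(atlas_group(atl$vnc, "mVAC")), "other")
  expect_equal(unname(atlas_group(atl$brain, c("IPS", "SPS"))),
               rep("posterior_slope", 2))
  expect_error(atlas_group(atl$vnc, "nonexistent"), "unknown")
})

test_that("polarity codes decode, re-encode, and reject malformed input", {
  dec <- decode_polarity(c("N", "S", "V", "B", "S1", "2", "0", ""))
  expect_equal(dec$polarity,
               c("none", "smooth", "varicose", "both", "smooth", "smooth",
                 "none", "none"))
  expect_equal(dec$intensity, c(0L, 2L, 2L, 2L, 1L, 2L, 0L, 0L))
  expect_equal(encode_polarity(dec$polarity, dec$intensity),
               c("N", "S", "V", "B", "S1", "S", "N", "N"))
  expect_error(decode_polarity("Q"), "unknown polarity code")
  expect_error(decode_polarity("N2"), "cannot carry an intensity")
  expect_error(encode_polarity("none", 2L), "must pair")
})

test_that("catalog validation enforces the record invariants", {
  rec <- data.frame(type_id = "DNp01", soma_group = "p", kind = "unique",
                    n_pairs = 1L, laterality = "ipsilateral", tract = "MTD")
  expect_s3_class(dn_catalog(rec), "dn_catalog")

  bad <- rec; bad$n_pairs <- 3L
  expect_error(dn_catalog(bad), "unique types must have n_pairs = 1")
  bad <- rec; bad$type_id <- "DNq01"; bad$soma_group <- "q"
  expect_error(dn_catalog(bad), "illegal soma-group letter")
  bad <- rbind(rec, rec)
  expect_error(dn_catalog(bad), "DNp01")
  bad <- rec; bad$tract <- "XYZ"
  expect_error(dn_catalog(bad), "tract")

  # annotations must reference atlas compartments
  codes <- matrix("S", 1, 1, dimnames = list("DNp01", "NOTANEUROPIL"))
  expect_error(dn_catalog(rec, brain = codes), "absent from the atlas")
})

test_that("CSV round trip is the identity on random catalogs", {
  for (seed in 1:5) {
    cat1 <- random_catalog(seed, n = 10)
    path <- withr::local_tempfile(fileext = ".csv")
    write_catalog(cat1, path)
    cat2 <- suppressMessages(parse_catalog(path))
    canon <- dnproj:::.canonicalize_catalog(cat1)
    expect_equal(cat2$records, canon$records)
    expect_equal(cat2$brain, canon$brain)
    expect_equal(cat2$vnc, canon$vnc)
  }
})

test_that("JSON and CSV emissions decode to identical catalogs", {
  cat1 <- random_catalog(99, n = 8)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_catalog(cat1, csv)
  write_catalog(cat1, json)
  from_csv <- suppressMessages(parse_catalog(csv))
  from_json <- suppressMessages(parse_catalog(json))
  expect_equal(from_csv$records, from_json$records)
  expect_equal(from_csv$brain, from_json$brain)
  expect_equal(from_csv$vnc, from_json$vnc)
})

test_that("an empty catalog writes a header-only file that re-parses", {
  empty <- dn_catalog(data.frame(type_id = character(0),
                                 soma_group = character(0),
                                 kind = character(0),
                                 n_pairs = integer(0),
                                 laterality = character(0),
                                 tract = character(0)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalog(empty, path)
  lines <- readLines(path)
  expect_length(lines, 1)  # header only
  reparsed <- parse_catalog(path)
  expect_equal(n_types(reparsed), 0)
})

test_that("parsing rejects duplicate ids and unknown columns", {
  cat1 <- toy_pathway_catalog()
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalog(cat1, path)
  tab <- read.csv(path, check.names = FALSE)
  dup <- rbind(tab, tab[1, ])
  dup_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(dup, dup_path, row.names = FALSE, quote = FALSE)
  expect_error(parse_catalog(dup_path), "DNg01")  # first row after sort

  tab$MYSTERY <- "S"
  bad_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, bad_path, row.names = FALSE, quote = FALSE)
  expect_error(parse_catalog(bad_path), "MYSTERY")
})

test_that("atlas YAML round trips", {
  atl <- load_default_atlases()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_atlas(atl$vnc, path)
  back <- read_atlas(path)
  expect_equal(as.data.frame(back), as.data.frame(atl$vnc))
  expect_equal(attr(back, "side"), "vnc")
})
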