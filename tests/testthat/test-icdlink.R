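links_fixture <- tibble::tibble(
  key1 = c("en:Cough", "de:Husten", "en:Fever"),
  key2 = c("de:Husten", "ru:Кашель", "de:Fieber")
)

test_that("link clusters are the symmetric-transitive closure", {
  cl <- link_clusters(links_fixture)
  cough <- cl$cluster[cl$key == "en:Cough"]
  expect_equal(cl$cluster[cl$key == "ru:Кашель"], cough)
  expect_equal(cl$cluster[cl$key == "de:Husten"], cough)
  expect_false(cl$cluster[cl$key == "en:Fever"] == cough)
  expect_equal(sort(unique(cl$cluster)), 1:2)
})

test_that("cross-language merge adds linked counterparts and is idempotent", {
  store <- tibble::tibble(
    id = c("e1", "d1", "r1", "d2"),
    language = c("en", "de", "ru", "de"),
    title = c("Cough", "Husten", "Кашель", "Fieber"),
    text = "T. T.",
    icd_codes = list(character(), character(), character(), character())
  )
  snap <- list(articles = store, langlinks = links_fixture)
  collected <- store[store$id == "e1", ]

  m1 <- merge_cross_language(collected, snap)
  expect_setequal(m1$articles$id, c("e1", "d1", "r1"))
  expect_equal(m1$articles$source_step[m1$articles$id == "d1"], "cross_link")
  # en:Fever is linked but absent from the collected English set, so d2
  # stays out; nothing is missing from the snapshot store
  expect_equal(m1$missing_links, 0)

  m2 <- merge_cross_language(m1$articles, snap)
  expect_equal(nrow(m2$articles), nrow(m1$articles))

  # a link to an article the snapshot does not hold is counted
  snap2 <- list(articles = store[store$id != "r1", ],
                langlinks = links_fixture)
  m3 <- merge_cross_language(store[store$id == "e1", ], snap2)
  expect_equal(m3$missing_links, 1)
  expect_setequal(m3$articles$id, c("e1", "d1"))
})

test_that("code resolution normalizes, validates and honours manual fixes", {
  arts <- tibble::tibble(
    id = c("a", "b", "c"),
    language = "en",
    title = c("Air embolism", "Broken", "Gaming disorder"),
    icd_codes = list(c(" o88.0 "), c("0.00"), character())
  )
  icd_map <- tibble::tibble(
    key = c("en:Air embolism", "en:Gaming disorder"),
    codes = c("T79.0", "C51,F63.8")
  )
  manual <- tibble::tibble(key = "en:Gaming disorder", code = "C51",
                           reason = "template misuse at source")

  expect_warning(
    res <- resolve_icd_codes(arts, icd_map, manual_exclusions = manual),
    "invalid"
  )
  expect_setequal(res$codes[[1]], c("O88.0", "T79.0"))
  expect_setequal(res$code_origin[[1]], c("direct", "metadata"))
  expect_equal(res$codes[[2]], character())   # 0.00 dropped as invalid
  expect_equal(res$codes[[3]], "F63.8")       # C51 manually excluded
})

test_that("code validation accepts real codes and rejects mangled ones", {
  expect_true(all(validate_icd_code(c("T79.0", "O88.0", "F20", "U07.1",
                                      "M54.5", "C51"))))
  expect_false(any(validate_icd_code(c("0.00", "f20", "F2", "F200",
                                       "20.0", ""))))
})

test_that("propagation forms a closure with union code sets", {
  arts <- tibble::tibble(
    id = c("e1", "d1", "r1"),
    language = c("en", "de", "ru"),
    title = c("Cough", "Husten", "Кашель"),
    codes = list("F20", "F20.0", character()),
    code_origin = list("direct", "metadata", character())
  )
  out <- propagate_codes(arts, links_fixture)
  for (i in 1:3) expect_setequal(out$codes[[i]], c("F20", "F20.0"))
  expect_equal(out$code_origin[[3]], c("propagated", "propagated"))
  # closure: second application changes nothing
  out2 <- propagate_codes(out, links_fixture)
  expect_equal(out2$codes, out$codes)
  # all-empty cluster stays empty
  empty <- tibble::tibble(
    id = c("e1", "d1"), language = c("en", "de"),
    title = c("Cough", "Husten"),
    codes = list(character(), character()),
    code_origin = list(character(), character())
  )
  expect_equal(lengths(propagate_codes(empty, links_fixture)$codes),
               c(0L, 0L))
})

test_that("chapter instances follow distinct leading letters", {
  arts <- tibble::tibble(
    id = c("air", "schiz", "none"),
    language = "en",
    codes = list(c("O88.0", "T79.0"), c("F20", "F25.1"), character())
  )
  inst <- assign_chapters(arts)
  expect_equal(inst$chapter[inst$id == "air"], c("O", "T"))
  expect_equal(inst$chapter[inst$id == "schiz"], "F")
  expect_false("none" %in% inst$id)
  # per-article instance count = number of distinct leading letters
  expect_equal(nrow(inst), 3)
})

test_that("group split partitions and reports two-decimal percentages", {
  arts <- tibble::tibble(
    language = c("en", "en", "en"),
    codes = list("F20", character(), "A00")
  )
  sp <- split_groups(arts)
  expect_equal(sp$summary$n_a, 2)
  expect_equal(sp$summary$pct_a, 66.67)
  expect_equal(sp$summary$pct_b, 33.33)
  expect_equal(sp$summary$n_total, 3)
  all_a <- split_groups(tibble::tibble(language = "de",
                                       codes = list("B01", "C02")))
  expect_equal(all_a$summary$pct_a, 100)
  expect_equal(all_a$summary$n_b, 0)
})

test_that("post-propagation group-A fraction matches the planted clusters", {
  d <- withr::local_tempdir()
  spec <- small_spec(seed = 907)
  truth <- generate_snapshot(spec, d)$truth
  snap <- load_snapshot(d)

  ann <- resolve_icd_codes(snap$articles, snap$icd_map)
  ann <- propagate_codes(ann, snap$langlinks)
  sp <- split_groups(ann)

  # every member of a coded cluster must end in group A, all others in B
  joined <- dplyr::left_join(sp$articles,
                             truth$articles[, c("id", "coded")], by = "id")
  art <- joined[!is.na(joined$coded), ]   # planted disease articles
  expect_equal(art$group == "A", art$coded)
})
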