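make_panel <- function(names_, len = 60, seed = 1) {
  set.seed(seed)
  seqs <- setNames(vapply(seq_along(names_), function(i) rand_protein(len), ""),
                   names_)
  reference_panel(seqs)
}

test_that("AGNC names parse and invalid ones are rejected", {
  p <- parse_aldh_name(c("OsALDH2B5", "ALDH12A1", "AtALDH3H1"))
  expect_identical(p$family, c(2L, 12L, 3L))
  expect_identical(p$subfamily, c("B", "A", "H"))
  expect_identical(p$member, c(5L, 1L, 1L))
  expect_identical(p$prefix, c("Os", "", "At"))
  expect_error(parse_aldh_name("ALDH2b5"), "do not parse")
  expect_error(parse_aldh_name("OsADH2B5"), "do not parse")
})

test_that("identity matrix equals element-wise recomputation and is symmetric", {
  set.seed(3)
  seqs <- setNames(vapply(1:4, function(i) rand_protein(50), ""),
                   paste0("s", 1:4))
  m <- identity_matrix(seqs)
  expect_identical(m, t(m))
  expect_identical(unname(diag(m)), rep(1, 4))
  for (i in 1:3) for (j in (i + 1):4) {
    aln <- nw_align(seqs[i], seqs[j])
    expect_equal(m[i, j], percent_identity(aln), tolerance = 1e-12)
  }
})

test_that("threshold semantics are strict at the family and subfamily boundaries", {
  # queries engineered to sit at exact identities against a single reference
  for (cfg in list(list(id = 41, expect_new_fam = FALSE),
                   list(id = 39, expect_new_fam = TRUE))) {
    pr <- pair_at_identity(100, cfg$id, seed = cfg$id)
    panel <- reference_panel(setNames(pr$ref, "ALDH2B1"))
    # guard: the construction really achieves the intended identity
    expect_equal(percent_identity(nw_align(pr$qry, pr$ref)), cfg$id / 100)
    asg <- assign_family(c(q = pr$qry), panel)
    expect_identical(asg$new_family, cfg$expect_new_fam)
    if (!cfg$expect_new_fam) {
      expect_identical(asg$family, 2L)
      expect_true(asg$new_subfamily)   # 0.41 < 0.60
    }
  }
  pr <- pair_at_identity(100, 61, seed = 61)
  panel <- reference_panel(setNames(pr$ref, "ALDH2B1"))
  expect_equal(percent_identity(nw_align(pr$qry, pr$ref)), 0.61)
  asg <- assign_family(c(q = pr$qry), panel)
  expect_identical(asg$family, 2L)
  expect_false(asg$new_subfamily)
  expect_identical(asg$subfamily, "B")

  # exactly at a threshold: "more than" is strict
  pr40 <- pair_at_identity(100, 40, seed = 40)
  panel <- reference_panel(setNames(pr40$ref, "ALDH2B1"))
  expect_equal(percent_identity(nw_align(pr40$qry, pr40$ref)), 0.40)
  expect_true(assign_family(c(q = pr40$qry), panel)$new_family)
})

test_that("raising thresholds never moves a query toward an existing group", {
  set.seed(77)
  panel <- make_panel(c("ALDH1A1", "ALDH2A1", "ALDH3A1"), len = 80, seed = 5)
  for (i in 1:6) {
    q <- c(q = rand_protein(80))
    lo <- suppressWarnings(assign_family(q, panel, thresholds(0.30, 0.50)))
    hi <- suppressWarnings(assign_family(q, panel, thresholds(0.45, 0.70)))
    if (lo$new_family) expect_true(hi$new_family)
    if (lo$new_subfamily) expect_true(hi$new_subfamily)
  }
})

test_that("margin-separated synthetic families classify without family errors", {
  fam <- simulate_families(n_families = 3, members_per_family = 4,
                           seq_length = 300, within_identity = 0.62,
                           between_identity = 0.05, seed = 101)
  # panel: first member of each family; queries: the rest
  firsts <- fam$truth$id[fam$truth$member == 1]
  panel_names <- sprintf("ALDH%dA1", fam$truth$family[match(firsts, fam$truth$id)])
  panel <- reference_panel(setNames(fam$records[firsts], panel_names))
  rest <- setdiff(fam$truth$id, firsts)
  res <- classify_queries(fam$records[rest], panel)
  truth_fam <- fam$truth$family[match(rest, fam$truth$id)]
  expect_identical(res$family, truth_fam)
  expect_false(any(res$new_family))
})

test_that("proposed names follow AGNC member, letter and family-number rules", {
  panel <- make_panel(c("ALDH2B1", "ALDH2B2", "ALDH2B3", "ALDH2B4"), seed = 2)
  # next member in an existing subfamily
  asg <- list(query_id = "q", query_seq = "NOTINPANEL",
              family = 2L, subfamily = "B",
              new_family = FALSE, new_subfamily = FALSE)
  nm <- propose_name(asg, "Os", panel)
  expect_identical(as.character(nm), "OsALDH2B5")

  # new subfamily: first unused letter after A-H
  panel3 <- make_panel(sprintf("ALDH3%s1", LETTERS[1:8]), seed = 3)
  asg3 <- list(query_id = "q", query_seq = "NOTINPANEL",
               family = 3L, subfamily = NA_character_,
               new_family = FALSE, new_subfamily = TRUE)
  expect_identical(as.character(propose_name(asg3, "Os", panel3)), "OsALDH3I1")

  # new family: smallest unused number at or above the floor
  asgN <- list(query_id = "q", query_seq = "NOTINPANEL",
               family = NA_integer_, subfamily = NA_character_,
               new_family = TRUE, new_subfamily = TRUE)
  expect_identical(as.character(propose_name(asgN, "Os", panel3)), "OsALDH1A1")
  expect_identical(as.character(propose_name(asgN, "Os", panel3,
                                             family_floor = 3L)), "OsALDH4A1")
})

test_that("two queries resolving to the same new subfamily number sequentially", {
  # q1 and q2 nearly identical to each other (0.95) but at 0.50 to the panel
  # exemplar: q1 founds subfamily B, q2 then joins it as member 2
  set.seed(55)
  base <- strsplit(rand_protein(200, names(B62_PARTNER)), "")[[1]]
  q1 <- paste(base, collapse = "")
  q2c <- base; i2 <- sample(200, 10); q2c[i2] <- B62_PARTNER[base[i2]]
  q2 <- paste(q2c, collapse = "")
  refc <- base; ir <- sample(200, 100); refc[ir] <- B62_PARTNER[base[ir]]
  panel <- reference_panel(setNames(paste(refc, collapse = ""), "ALDH2A1"))

  res <- classify_queries(setNames(c(q1, q2), c("q1", "q2")), panel)
  expect_identical(res$family, c(2L, 2L))
  expect_identical(res$new_subfamily, c(TRUE, FALSE))
  expect_identical(res$subfamily, c("B", "B"))
  expect_identical(res$member, c(1L, 2L))
  expect_identical(res$proposed_name, c("OsALDH2B1", "OsALDH2B2"))
})

test_that("re-classifying a panel member returns its own name", {
  panel <- make_panel(c("OsALDH2B1", "OsALDH2C1", "OsALDH3E1"), seed = 9)
  for (i in seq_len(nrow(panel))) {
    asg <- assign_family(setNames(panel$seq[i], panel$name[i]), panel)
    expect_equal(asg$best_family_identity, 1)
    nm <- propose_name(asg, "Os", panel)
    expect_identical(as.character(nm), panel$name[i])
  }
})

test_that("classification is deterministic and ties warn toward the lower family", {
  pr <- pair_at_identity(100, 50, seed = 123)
  panel <- reference_panel(setNames(c(pr$ref, pr$ref), c("ALDH5A1", "ALDH3A1")))
  expect_warning(asg <- assign_family(c(q = pr$qry), panel), "ties")
  expect_identical(asg$family, 3L)
  asg2 <- suppressWarnings(assign_family(c(q = pr$qry), panel))
  expect_identical(asg$best_reference, asg2$best_reference)
})

test_that("superfamily summary reproduces the packaged table's structure", {
  s <- summarize_superfamily(aldh_table1())
  expect_identical(s$n_genes, 21L)
  expect_identical(s$n_families, 10L)
  expect_identical(s$families_multi,
                   c(`2` = 5L, `3` = 5L, `10` = 2L, `12` = 2L, `18` = 2L))
  expect_identical(sort(s$families_single), c(5L, 6L, 7L, 11L, 22L))
  expect_identical(s$largest_two_total, 10L)
  expect_identical(sum(s$counts), s$n_genes)

  s1 <- summarize_superfamily("OsALDH7B6")
  expect_identical(s1$n_genes, 1L)
  expect_identical(s1$n_families, 1L)
})
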