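test_that("pattern compiler handles the core PROSITE constructs", {
  p <- compile_pattern("T1", "G-[QE]-C", anchor_index = 3)
  hits <- scan_motifs(c(s = "AGQCA"), p)
  expect_identical(hits$start, 2L)
  expect_identical(hits$end, 4L)
  expect_identical(hits$matched, "GQC")
  expect_identical(hits$anchor_pos, 4L)
  expect_identical(hits$anchor_residue, "C")

  # x(2) matches every 2-mer: n-1 overlapping hits
  p2 <- compile_pattern("T2", "x(2)")
  expect_identical(nrow(scan_motifs(c(s = "ACDEF"), p2)), 4L)

  # negation
  p3 <- compile_pattern("T3", "{C}")
  expect_identical(nrow(scan_motifs(c(s = "C"), p3)), 0L)
  expect_identical(nrow(scan_motifs(c(s = "A"), p3)), 1L)

  # terminal anchors
  pstart <- compile_pattern("T4", "<A-C")
  expect_identical(scan_motifs(c(s = "ACAC"), pstart)$start, 1L)
  pend <- compile_pattern("T5", "A-C>")
  expect_identical(scan_motifs(c(s = "ACAC"), pend)$start, 3L)

  expect_error(compile_pattern("bad", "G-[qe]-C"), "parse error")
  expect_error(compile_pattern("bad", "G--C"), "empty element")
  expect_error(compile_pattern("bad", "x(2)-C", anchor_index = 2),
               NA) # fixed-length prefix (x(2) has min == max) is allowed
  expect_error(compile_pattern("bad", "x(1,3)-C", anchor_index = 2),
               "fixed-length")
})

test_that("empty pattern list and scan of clean sequences return empty hits", {
  expect_identical(nrow(scan_motifs(c(s = "ACDEF"), list())), 0L)
})

test_that("scan agrees with a brute-force matcher on random patterns and strings", {
  alphabet <- c("A", "C", "D", "E")
  set.seed(1234)
  n_checked <- 0L
  for (trial in 1:25) {
    elems <- random_elems(sample(1:3, 1), alphabet)
    pat <- compile_pattern("RND", elems_to_prosite(elems))
    # exhaustive over all strings of lengths 1..3, sampled for 4..8
    strs <- c(
      unlist(lapply(1:3, function(k)
        apply(expand.grid(rep(list(alphabet), k)), 1, paste, collapse = ""))),
      vapply(4:8, function(k) rand_protein(k, alphabet), character(1)))
    for (s in strs) {
      got <- scan_motifs(setNames(s, "s"), pat)$start
      want <- bf_pattern_starts(s, elems)
      expect_identical(got, as.integer(want),
                       label = sprintf("pattern '%s' on '%s'", pat$pattern, s))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 2000L)
})

test_that("planted motif instances are recovered at their planted anchors", {
  pat <- compile_pattern("PS-like", "G-[QE]-C-x-[AG]", anchor_index = 3)
  set.seed(99)
  for (pos in c(1L, 271L, 496L)) {
    base <- rand_protein(500, c("K", "R", "H", "W"))  # cannot contain the motif
    planted <- plant_motif(base, "GQCWA", pos, anchor_offset = 2L)
    hits <- scan_motifs(setNames(planted$seq, "s"), pat)
    expect_true(planted$truth$anchor_pos %in% hits$anchor_pos)
    expect_identical(nrow(hits), 1L)
  }
  # a planted instance containing two overlapping occurrences yields both hits
  base <- rand_protein(40, c("K", "R", "H", "W"))
  p1 <- plant_motif(base, "GQCQC", 12)
  pat2 <- compile_pattern("PS-like2", "[GC]-Q-C", anchor_index = 3)
  hits <- scan_motifs(setNames(p1$seq, "s"), pat2)
  expect_true(all(c(12L, 14L) %in% hits$start))
})

test_that("false-positive counts on random sequences match the match probability", {
  # P(hit at a position) for pattern A-C on uniform 4-letter residues = 1/16
  pat <- compile_pattern("AC", "A-C")
  set.seed(7)
  len <- 500L; nseq <- 200L
  counts <- vapply(seq_len(nseq), function(i) {
    s <- rand_protein(len, c("A", "C", "D", "E"))
    nrow(scan_motifs(setNames(s, "s"), pat))
  }, numeric(1))
  expected <- (len - 1) / 16
  se <- sd(counts) / sqrt(nseq)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("reference-position mapping is the identity on self and shifts under padding", {
  set.seed(3)
  ref <- rand_protein(120)
  expect_identical(map_reference_position(ref, ref, 45L), 45L)
  padded <- paste0(rand_protein(10), ref)
  expect_identical(map_reference_position(padded, ref, 45L), 55L)
  # a deletion spanning the site leaves it unmapped
  del <- paste0(substring(ref, 1, 30), substring(ref, 61, 120))
  expect_true(is.na(map_reference_position(del, ref, 45L)))
  expect_error(map_reference_position(ref, ref, 0L), "out of range")
  expect_error(map_reference_position(ref, ref, 121L), "out of range")
})

test_that("cofactor rule reproduces the three printed groups and is total", {
  expect_identical(classify_cofactor("A", "VALTA"), "NADP_preferring")
  expect_identical(classify_cofactor("E", "WWWWW"), "NAD_preferring")
  expect_identical(classify_cofactor("R", "AAAAA"), "dual_switching")
  # site residue dominates: R wins even with charged residues nearby
  expect_identical(classify_cofactor("R", "EEKEE"), "dual_switching")
  # K is in the default charged set and triggers the NAD call
  expect_identical(classify_cofactor("A", "VAKTA"), "NAD_preferring")
  # totality: every residue/window yields exactly one of the four calls
  set.seed(12)
  calls <- c("NADP_preferring", "NAD_preferring", "dual_switching", "unresolved")
  for (i in 1:50) {
    res <- classify_cofactor(sample(AA20_TEST, 1), rand_protein(5))
    expect_length(res, 1L)
    expect_true(res %in% calls)
  }
  expect_identical(classify_cofactor("G", "GGGGG"), "unresolved")
})

test_that("end-to-end cofactor call maps the site through an alignment", {
  set.seed(8)
  left <- rand_protein(194, setdiff(AA20_TEST, c("E", "K", "R")))
  right <- rand_protein(105, setdiff(AA20_TEST, c("E", "K", "R")))
  reference <- paste0(left, "E", right)            # E at position 195
  stopifnot(substring(reference, 195, 195) == "E")

  # query: same scaffold with the site region replaced by uncharged residues
  q_nadp <- paste0(substring(reference, 1, 192), "AVLTA",
                   substring(reference, 198, 300))
  call1 <- cofactor_call(c(q = q_nadp), reference)
  expect_identical(call1$call, "NADP_preferring")
  expect_identical(call1$e195_query_pos, 195L)

  call2 <- cofactor_call(c(q = reference), reference)
  expect_identical(call2$call, "NAD_preferring")
  expect_identical(call2$e195_residue, "E")

  q_dual <- paste0(substring(reference, 1, 194), "R", substring(reference, 196, 300))
  expect_identical(cofactor_call(c(q = q_dual), reference)$call, "dual_switching")
})

test_that("catalytic pair geometry reports separation or incompleteness", {
  hits <- data.frame(anchor_pos = c(271L, 361L), anchor_residue = c("C", "E"))
  g <- catalytic_pair_geometry(hits)
  expect_true(g$complete)
  expect_identical(g$separation, 90L)
  expect_identical(g$classification, "separated")

  hits2 <- data.frame(anchor_pos = c(303L, 269L), anchor_residue = c("C", "E"))
  expect_identical(catalytic_pair_geometry(hits2)$separation, 34L)

  g3 <- catalytic_pair_geometry(data.frame(anchor_pos = 10L, anchor_residue = "C"))
  expect_false(g3$complete)
  expect_identical(g3$classification, "incomplete")

  # directly consecutive sites are adjacent
  g4 <- catalytic_pair_geometry(data.frame(anchor_pos = c(100L, 101L),
                                           anchor_residue = c("C", "E")))
  expect_identical(g4$classification, "adjacent")
})

test_that("packaged pattern config loads and anchors the catalytic residues", {
  pats <- read_pattern_config()
  expect_length(pats, 2L)
  accs <- vapply(pats, `[[`, "", "accession")
  expect_setequal(accs, c("PS00070", "PS00687"))
  # planting a conforming instance is recovered with the right anchor residue
  glu <- pats[[which(accs == "PS00687")]]
  inst <- "LELGGKST"   # conforms to the glutamate-site pattern
  seqp <- plant_motif(rand_protein(300, c("W", "H", "R", "Y")), inst, 150)
  hit <- scan_motifs(setNames(seqp$seq, "s"), glu)
  expect_identical(hit$anchor_residue, "E")
  expect_identical(hit$anchor_pos, 151L)
})
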