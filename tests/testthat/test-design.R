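# Primer/probe design: window scanning, candidate enumeration, assay-set
# ranking, control design, in-silico specificity.

# a small labeled alignment with a dense diagnostic region built from the
# synthetic generator (deterministic); the conspecific outlier lineage is
# relabeled nontarget so the design targets the main haplogroup only
design_fixture <- function(seed = 2) {
  sim <- generate_barcode_dataset(barcode_sim_config(), seed)
  tab <- as.data.frame(sim$table)
  outl <- sim$truth$sample_id[sim$truth$lineage == "outlier"]
  tab$group[tab$sample_id %in% outl] <- "nontarget"
  list(sim = sim, aln = sim$alignment,
       table = as_sample_table(tab, sim$alignment))
}

test_that("oligo_constraints validates overrides", {
  cn <- oligo_constraints()
  expect_s3_class(cn, "oligo_constraints")
  cn2 <- oligo_constraints(max_poly_x = 4)
  expect_identical(cn2$max_poly_x, 4)
  expect_error(oligo_constraints(bogus = 1), "unknown constraint")
  expect_error(oligo_constraints(primer_tm = c(min = 60, opt = 55, max = 65)),
               "min <= opt <= max")
})

test_that("snv_density_scan scores segments by the documented formula", {
  fx <- design_fixture()
  wins <- snv_density_scan(fx$aln, fx$table)
  expect_s3_class(wins, "design_windows")
  expect_gt(nrow(wins), 0)
  # independent score recomputation from first principles
  m <- unclass(fx$aln)
  tgt <- fx$table$sample_id[fx$table$group == "target"]
  non <- fx$table$sample_id[fx$table$group == "nontarget"]
  is_fixed <- vapply(seq_len(ncol(m)), function(j) {
    ts <- unique(m[tgt, j])
    length(ts) == 1 && !(ts %in% m[non, j])
  }, TRUE)
  is_var <- vapply(seq_len(ncol(m)), function(j)
    length(unique(m[tgt, j])) > 1, TRUE)
  for (i in seq_len(min(3, nrow(wins)))) {
    s <- wins$segment_start[i]; e <- wins$segment_end[i]
    expect_equal(wins$fixed_diffs[i], sum(is_fixed[s:e]))
    expect_equal(wins$intra_target_snvs[i], sum(is_var[s:e]))
    expect_equal(wins$score[i],
                 sum(is_fixed[s:e]) - sum(is_var[s:e]))
  }
  # the top segment's score is the global maximum over all placements
  allscores <- vapply(seq_len(ncol(m) - 125 + 1), function(s)
    sum(is_fixed[s:(s + 124)]) - sum(is_var[s:(s + 124)]), 0)
  expect_equal(wins$score[1], max(allscores))
})

test_that("oligo windows maximize covered fixed differences (brute force)", {
  fx <- design_fixture()
  W <- 30
  wins <- snv_density_scan(fx$aln, fx$table, oligo_window = W)
  fixed <- attr(wins, "fixed_positions")
  w1 <- wins[1, ]
  cover <- function(st) sum(fixed >= st & fixed <= st + W - 1)
  got <- cover(w1$fwd_start) + cover(w1$probe_start) + cover(w1$rev_start)
  # brute force over all ordered non-overlapping window triples
  starts <- w1$segment_start:(w1$segment_end - W + 1)
  best <- 0
  for (f in starts) for (p in starts[starts >= f + W])
    for (r in starts[starts >= p + W])
      best <- max(best, cover(f) + cover(p) + cover(r))
  expect_equal(got, best)
  # geometry invariants
  expect_gte(w1$probe_start, w1$fwd_start + W)
  expect_gte(w1$rev_start, w1$probe_start + W)
  expect_lte(w1$rev_start + W - 1, w1$segment_end)
})

test_that("snv_density_scan warns and returns empty without signal", {
  aln <- as_alignment(stats::setNames(
    rep(strrep("ACGT", 40), 3), c("t1", "n1", "o1")))
  tab <- mk_table(rownames(aln), c("target", "nontarget", "outgroup"))
  expect_warning(wins <- snv_density_scan(aln, tab, segment_len = 100),
                 "no segment")
  expect_identical(nrow(wins), 0L)
  expect_error(snv_density_scan(aln, tab, segment_len = 1000), "shorter")
})

test_that("enumerate_candidates equals brute-force enumeration", {
  set.seed(14)
  cn <- oligo_constraints()
  brute <- function(w, role) {
    lenb <- if (role == "probe") cn$probe_len else cn$primer_len
    tmb <- if (role == "probe") cn$probe_tm else cn$primer_tm
    out <- list()
    n <- nchar(w)
    for (len in lenb["min"]:min(lenb["max"], n)) for (s in 1:(n - len + 1)) {
      top <- substr(w, s, s + len - 1)
      o <- if (role == "reverse") reverse_complement(top) else top
      tm <- tm_nearest_neighbor(o, cn$mono, cn$div, cn$dntp, cn$ct)
      gc <- gc_percent(o)
      sc <- structure_screen(o, mono = cn$mono, div = cn$div,
                             dntp = cn$dntp, ct = cn$ct)
      if (tm < tmb["min"] || tm > tmb["max"]) next
      if (gc < cn$gc["min"] || gc > cn$gc["max"]) next
      if (sc$poly_x > cn$max_poly_x) next
      if (sc$three_prime_stability > cn$max_3p_stability) next
      if (sc$self_dimer_tm > cn$max_dimer_tm) next
      pen <- abs(tm - tmb["opt"]) + 0.05 * abs(gc - cn$gc["opt"]) +
        0.2 * abs(len - lenb["opt"])
      out[[length(out) + 1]] <- data.frame(sequence = o, start = s,
                                           end = s + len - 1, penalty = pen,
                                           stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, out)
    if (is.null(out)) return(out)
    out[order(out$penalty, out$start, out$end - out$start + 1), ,
        drop = FALSE]
  }
  for (role in c("forward", "reverse", "probe")) {
    w <- rand_seq(40)
    got <- enumerate_candidates(w, cn, role)
    want <- brute(w, role)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      want <- utils::head(want, cn$candidates_per_window)
      expect_identical(got$sequence, want$sequence)
      expect_equal(got$start, want$start)
      expect_equal(got$penalty, want$penalty)
    }
  }
  # offset shifts reported coordinates only
  w <- rand_seq(40)
  a <- enumerate_candidates(w, cn, "forward", offset = 1)
  b <- enumerate_candidates(w, cn, "forward", offset = 101)
  if (nrow(a)) {
    expect_equal(b$start, a$start + 100)
    expect_identical(b$sequence, a$sequence)
  }
  # reverse candidates are reverse complements of the top strand
  r <- enumerate_candidates(w, cn, "reverse")
  if (nrow(r)) {
    top <- substr(w, r$start[1], r$end[1])
    expect_identical(r$sequence[1], reverse_complement(top))
  }
  expect_identical(nrow(enumerate_candidates("ACGT", cn, "forward")), 0L)
})

test_that("discriminative_support end-weights terminal positions", {
  aln <- as_alignment(stats::setNames(rep(strrep("A", 40), 2),
                                      c("t", "n")))
  tab <- mk_table(c("t", "n"), c("target", "nontarget"))
  # fixed positions injected directly: 11 and 27 are within 5 of the
  # footprint ends (weight 2), 20 is interior (weight 1)
  ds <- discriminative_support(10, 30, aln, tab, fixed = c(11, 20, 27))
  expect_identical(ds$count, 3L)
  expect_identical(ds$positions, c(11, 20, 27))
  expect_identical(ds$end_weighted_score, 5)
  # all-interior positions score exactly their count
  ds2 <- discriminative_support(1, 40, aln, tab, fixed = c(10, 20, 30))
  expect_identical(ds2$end_weighted_score, 3)
  expect_error(discriminative_support(0, 10, aln, tab, fixed = 5),
               "outside")
})

test_that("rank_assay_sets orders feasible triples deterministically", {
  fx <- design_fixture()
  sets <- design_assay(fx$aln, fx$table)
  expect_s3_class(sets, "assay_sets")
  expect_gt(nrow(sets), 0)
  s1 <- sets[1, ]
  # feasible geometry and probe-Tm dominance
  expect_true(all(sets$fwd_end < sets$probe_start))
  expect_true(all(sets$probe_end < sets$rev_start))
  expect_true(all(sets$probe_tm > sets$fwd_tm))
  expect_true(all(sets$probe_tm > sets$rev_tm))
  # rank 1 attains the maximum discriminative total
  expect_identical(s1$total_discriminative,
                   max(sets$total_discriminative))
  expect_identical(sets$rank, seq_len(nrow(sets)))
  # the ranking is invariant to candidate input order
  wins <- snv_density_scan(fx$aln, fx$table)
  W <- attr(wins, "oligo_window")
  tgt <- fx$table$sample_id[fx$table$group == "target"]
  cons <- consensus_sequence(fx$aln, tgt)
  w1 <- wins[1, ]
  cands <- do.call(rbind, list(
    enumerate_candidates(substr(cons, w1$fwd_start, w1$fwd_start + W - 1),
                         role = "forward", offset = w1$fwd_start),
    enumerate_candidates(substr(cons, w1$probe_start,
                                w1$probe_start + W - 1),
                         role = "probe", offset = w1$probe_start),
    enumerate_candidates(substr(cons, w1$rev_start, w1$rev_start + W - 1),
                         role = "reverse", offset = w1$rev_start)))
  set.seed(9)
  shuf <- cands[sample(nrow(cands)), ]
  r1 <- rank_assay_sets(cands, oligo_constraints(), fx$aln, fx$table)
  r2 <- rank_assay_sets(shuf, oligo_constraints(), fx$aln, fx$table)
  rownames(r1) <- rownames(r2) <- NULL
  expect_identical(r1, r2)
})

test_that("rank_assay_sets reports diagnostics when infeasible", {
  fx <- design_fixture()
  empty <- rank_assay_sets(
    data.frame(sequence = character(), role = character(),
               start = integer(), end = integer(), tm_nn = numeric(),
               self_dimer_tm = numeric(), hairpin = integer(),
               self_annealing = integer()),
    oligo_constraints(), fx$aln, fx$table)
  expect_identical(nrow(empty), 0L)
  expect_true(length(attr(empty, "diagnostics")) >= 1)
})

test_that("control assay stays in conserved sequence below diagnostic Tm", {
  fx <- design_fixture()
  diag_assay <- design_assay(fx$aln, fx$table)[1, ]
  ctrl <- design_control_assay(fx$sim$control_alignment, fx$table,
                               diag_assay)
  expect_lte(ctrl$fwd_tm, diag_assay$fwd_tm)
  expect_lte(ctrl$probe_tm, diag_assay$probe_tm)
  expect_lte(ctrl$rev_tm, diag_assay$rev_tm)
  expect_true(ctrl$fwd_end < ctrl$probe_start)
  expect_true(ctrl$probe_end < ctrl$rev_start)
  # every control footprint column is invariant across the ingroup panel
  m <- unclass(fx$sim$control_alignment)
  ingroup <- fx$table$sample_id[fx$table$group != "outgroup"]
  cols <- c(ctrl$fwd_start:ctrl$fwd_end, ctrl$probe_start:ctrl$probe_end,
            ctrl$rev_start:ctrl$rev_end)
  expect_true(all(apply(m[ingroup, cols], 2,
                        function(col) length(unique(col)) == 1)))
  # an alignment with no conserved run long enough errors
  set.seed(4)
  noisy <- as_alignment(c(a = rand_seq(60), b = rand_seq(60)))
  tab <- mk_table(c("a", "b"), c("target", "nontarget"))
  expect_error(design_control_assay(noisy, tab, diag_assay), "conserved")
})

test_that("in_silico_specificity applies the mismatch rules", {
  # assay with known footprints on a 60-column panel
  base <- strsplit(strrep("ACGT", 15), "")[[1]]
  mk <- function(v) paste(v, collapse = "")
  assay <- data.frame(
    fwd_sequence = mk(base[1:18]), fwd_start = 1, fwd_end = 18,
    probe_sequence = mk(base[21:40]), probe_start = 21, probe_end = 40,
    rev_sequence = reverse_complement(mk(base[43:60])), rev_start = 43,
    rev_end = 60, stringsAsFactors = FALSE)
  perfect <- base
  internal1 <- base; internal1[5] <- "T"             # 1 fwd internal mm
  internal3 <- base; internal3[c(3, 5, 7)] <- "T"    # 3 fwd mms
  threep <- base; threep[18] <- "T"                  # fwd 3'-end mm
  rev3p <- base; rev3p[43] <- "A"                    # rev 3'-end mm (left)
  probe2 <- base; probe2[c(26, 30)] <- "A"           # 2 probe mms
  gapped <- base; gapped[30] <- "-"                  # gap = probe mm
  ambig <- base; ambig[5] <- "N"                     # N covers -> match
  panel <- as_alignment(c(ok = mk(perfect), i1 = mk(internal1),
                          i3 = mk(internal3), f3p = mk(threep),
                          r3p = mk(rev3p), p2 = mk(probe2),
                          gp = mk(gapped), am = mk(ambig)))
  sp <- in_silico_specificity(assay, panel)
  pred <- stats::setNames(sp$predicted_amplification, sp$sample_id)
  expect_true(pred[["ok"]])
  expect_true(pred[["i1"]])
  expect_false(pred[["i3"]])   # 3 > 2 primer mismatches
  expect_false(pred[["f3p"]])  # mismatch in forward 3' window
  expect_false(pred[["r3p"]])  # mismatch in reverse 3' window
  expect_false(pred[["p2"]])   # 2 > 1 probe mismatches
  expect_true(pred[["am"]])    # IUPAC cover counts as a match
  expect_identical(sp$probe_mm[sp$sample_id == "gp"], 1L)
  expect_identical(sp$fwd_mm[sp$sample_id == "i3"], 3L)
  bad <- assay; bad$rev_end <- 100
  expect_error(in_silico_specificity(bad, panel), "outside")
})
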