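# Diagnostic primer/probe design: SNV-density window scanning on a labeled
# alignment, constraint-based candidate enumeration on the target consensus,
# discriminative scoring, assay-set ranking, control-assay design, and local
# in-silico specificity against a sequence panel.

#' Primer/probe design constraints
#'
#' Defaults mirror a conventional TaqMan design parameterization: 50 mM
#' monovalent salt (1.5 mM divalent), 50 nM primer strands, 0.6 mM dNTP;
#' primer Tm 50/55.5/60 (min/opt/max, nearest-neighbor engine), probe Tm
#' 57/60/63; GC% 20/50/80; primer length 14/22/35 nt, probe length
#' 18/20/36 nt; maximum acceptable dimer Tm 47; maximum single-base run 5;
#' maximum 3'-pentamer duplex stability 9 kcal/mol; 5 candidates kept per
#' window.
#'
#' @param ... overrides for any listed field.
#' @return list of class `oligo_constraints`.
#' @export
oligo_constraints <- function(...) {
  def <- list(
    mono = 0.05, div = 0.0015, dntp = 6e-4, ct = 5e-8,
    primer_tm = c(min = 50, opt = 55.5, max = 60),
    probe_tm = c(min = 57, opt = 60, max = 63),
    gc = c(min = 20, opt = 50, max = 80),
    primer_len = c(min = 14, opt = 22, max = 35),
    probe_len = c(min = 18, opt = 20, max = 36),
    max_dimer_tm = 47,
    max_poly_x = 5,
    max_3p_stability = 9,
    candidates_per_window = 5)
  ov <- list(...)
  bad <- setdiff(names(ov), names(def))
  if (length(bad)) stop("unknown constraint(s): ", paste(bad, collapse = ", "))
  def[names(ov)] <- ov
  for (f in c("primer_tm", "probe_tm", "gc", "primer_len", "probe_len")) {
    v <- def[[f]]
    if (!(v["min"] <= v["opt"] && v["opt"] <= v["max"]))
      stop("constraint ", f, " must satisfy min <= opt <= max")
  }
  structure(def, class = "oligo_constraints")
}

# columns (1-based) variable within a set of rows, and columns fixed-different
# between target and nontarget rows
variable_columns <- function(aln, ids) {
  m <- unclass(aln)[ids, , drop = FALSE]
  which(apply(m, 2, function(col) length(unique(col)) > 1))
}

#' Scan an alignment for diagnostic design windows
#'
#' Every placement of a `segment_len` segment is scored as (number of fixed
#' target/nontarget differences) - `lambda` x (number of columns variable
#' within the target group). Within each positively scoring segment the
#' forward/probe/reverse oligo windows (each `oligo_window` columns,
#' non-overlapping, in left-to-right order) are placed to maximize the summed
#' count of fixed differences they cover. Segments are returned in
#' deterministic order: score descending, then leftmost.
#'
#' @param aln a `barcode_aln`.
#' @param table a `sample_table`.
#' @param segment_len segment length in columns (typically 100-150;
#'   default 125).
#' @param oligo_window oligo window width (default 30).
#' @param lambda penalty weight on intra-target variable columns
#'   (default 1).
#' @return data.frame of class `design_windows` (one row per segment:
#'   `segment_start`, `segment_end`, `score`, `fixed_diffs`,
#'   `intra_target_snvs`, `fwd_start`, `probe_start`, `rev_start`, all
#'   1-based), with attributes `fixed_positions` and `oligo_window`. Empty
#'   (with a warning) when no segment scores positively.
#' @param max_segments cap on the number of top-scoring segments for which
#'   window placement is computed (default 25).
#' @export
snv_density_scan <- function(aln, table, segment_len = 125,
                             oligo_window = 30, lambda = 1.0,
                             max_segments = 25) {
  table <- as_sample_table(as.data.frame(table), aln)
  tgt <- intersect(group_ids(table, "target"), rownames(aln))
  non <- intersect(group_ids(table, "nontarget"), rownames(aln))
  if (!length(tgt) || !length(non))
    stop("need at least one target and one nontarget sample")
  L <- ncol(aln)
  if (L < segment_len) stop("alignment shorter than segment_len")
  fixed <- fixed_difference_positions(aln, table)
  intra <- variable_columns(aln, tgt)
  isfix <- integer(L); isfix[fixed] <- 1L
  isvar <- integer(L); isvar[intra] <- 1L
  cf <- c(0, cumsum(isfix)); cv <- c(0, cumsum(isvar))
  starts <- seq_len(L - segment_len + 1)
  nf <- cf[starts + segment_len] - cf[starts]
  nv <- cv[starts + segment_len] - cv[starts]
  score <- nf - lambda * nv
  keep <- which(score > 0)
  if (!length(keep)) {
    warning("no segment with positive score")
    out <- data.frame(segment_start = integer(), segment_end = integer(),
                      score = numeric(), fixed_diffs = integer(),
                      intra_target_snvs = integer(), fwd_start = integer(),
                      probe_start = integer(), rev_start = integer())
    attr(out, "fixed_positions") <- fixed
    attr(out, "oligo_window") <- oligo_window
    class(out) <- c("design_windows", "data.frame")
    return(out)
  }
  keep <- keep[order(-score[keep], keep)]
  keep <- utils::head(keep, max_segments)
  W <- oligo_window
  rows <- lapply(keep, function(s) {
    e <- s + segment_len - 1
    if ((e - s + 1) < 3 * W) return(NULL)
    ws <- s:(e - W + 1)
    nw <- length(ws)
    if (nw < 2 * W + 1) return(NULL)
    wscore <- cf[ws + W] - cf[ws]
    # prefix/suffix argmax of window coverage (ties -> leftmost)
    pre <- integer(nw); b <- -Inf
    for (k in 1:nw) {
      if (wscore[k] > b) { b <- wscore[k]; pre[k] <- k }
      else pre[k] <- pre[k - 1]
    }
    suf <- integer(nw); b <- -Inf
    for (k in nw:1) {
      if (wscore[k] >= b) { b <- wscore[k]; suf[k] <- k }
      else suf[k] <- suf[k + 1]
    }
    # sweep the probe window; flanks take their argmax coverage; ties prefer
    # higher forward then probe coverage, then leftmost probe
    lex_gt <- function(a, b) {
      d <- which(a != b)
      length(d) > 0 && a[d[1]] > b[d[1]]
    }
    best <- NULL
    for (p in (W + 1):(nw - W)) {
      f <- pre[p - W]; r <- suf[p + W]
      key <- c(wscore[f] + wscore[p] + wscore[r], wscore[f], wscore[p], -p)
      if (is.null(best) || lex_gt(key, best$key))
        best <- list(key = key, f = f, p = p, r = r)
    }
    if (is.null(best)) return(NULL)
    data.frame(segment_start = s, segment_end = e,
               score = score[s], fixed_diffs = nf[s],
               intra_target_snvs = nv[s],
               fwd_start = ws[1] + best$f - 1,
               probe_start = ws[1] + best$p - 1,
               rev_start = ws[1] + best$r - 1)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(segment_start = integer(), segment_end = integer(),
                      score = numeric(), fixed_diffs = integer(),
                      intra_target_snvs = integer(), fwd_start = integer(),
                      probe_start = integer(), rev_start = integer())
  attr(out, "fixed_positions") <- fixed
  attr(out, "oligo_window") <- oligo_window
  class(out) <- c("design_windows", "data.frame")
  out
}

#' Enumerate oligo candidates within a window
#'
#' Every substring of the window consensus whose length lies within the
#' role's bounds is checked against the hard constraints: nearest-neighbor
#' Tm within the role's range, GC% within range, poly-X run, 3'-pentamer
#' stability, and self-dimer Tm. Passing candidates are penalized by distance
#' from the optima (`|Tm - opt| + 0.05 |GC - opt| + 0.2 |len - opt|`) and the
#' best `candidates_per_window` are returned. Reverse-role candidates are the
#' reverse complement of the top strand (their coordinates still refer to the
#' top strand).
#'
#' @param window_seq consensus sequence of the window (top strand).
#' @param constraints an [oligo_constraints()].
#' @param role one of `forward`, `reverse`, `probe`.
#' @param offset 1-based alignment coordinate of the first window base.
#' @return data.frame of candidates: `sequence`, `role`, `start`, `end`,
#'   `length`, `tm_nn`, `gc`, `poly_x`, `three_prime_stability`,
#'   `self_dimer_tm`, `hairpin`, `self_annealing`, `penalty`.
#' @export
enumerate_candidates <- function(window_seq, constraints = oligo_constraints(),
                                 role = c("forward", "reverse", "probe"),
                                 offset = 1) {
  role <- match.arg(role)
  cn <- constraints
  lenb <- if (role == "probe") cn$probe_len else cn$primer_len
  tmb <- if (role == "probe") cn$probe_tm else cn$primer_tm
  empty <- data.frame(sequence = character(), role = character(),
                      start = integer(), end = integer(), length = integer(),
                      tm_nn = numeric(), gc = numeric(), poly_x = integer(),
                      three_prime_stability = numeric(),
                      self_dimer_tm = numeric(), hairpin = integer(),
                      self_annealing = integer(), penalty = numeric(),
                      stringsAsFactors = FALSE)
  w <- toupper(window_seq)
  n <- nchar(w)
  if (n < lenb["min"]) return(empty)
  rows <- list()
  for (len in lenb["min"]:min(lenb["max"], n)) {
    for (s in 1:(n - len + 1)) {
      top <- substr(w, s, s + len - 1)
      if (grepl("[^ACGT]", top)) next
      oseq <- if (role == "reverse") reverse_complement(top) else top
      tm <- tm_nearest_neighbor(oseq, cn$mono, cn$div, cn$dntp, cn$ct)
      if (tm < tmb["min"] || tm > tmb["max"]) next
      gc <- gc_percent(oseq)
      if (gc < cn$gc["min"] || gc > cn$gc["max"]) next
      sc <- structure_screen(oseq, mono = cn$mono, div = cn$div,
                             dntp = cn$dntp, ct = cn$ct)
      if (sc$poly_x > cn$max_poly_x) next
      if (sc$three_prime_stability > cn$max_3p_stability) next
      if (sc$self_dimer_tm > cn$max_dimer_tm) next
      pen <- abs(tm - tmb["opt"]) + 0.05 * abs(gc - cn$gc["opt"]) +
        0.2 * abs(len - lenb["opt"])
      rows[[length(rows) + 1]] <- data.frame(
        sequence = oseq, role = role,
        start = offset + s - 1, end = offset + s + len - 2, length = len,
        tm_nn = tm, gc = gc, poly_x = sc$poly_x,
        three_prime_stability = sc$three_prime_stability,
        self_dimer_tm = sc$self_dimer_tm, hairpin = sc$hairpin,
        self_annealing = sc$self_annealing, penalty = pen,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$penalty, out$start, out$length), , drop = FALSE]
  utils::head(out, cn$candidates_per_window)
}

#' Discriminative support of an oligo footprint
#'
#' Counts the fixed target/nontarget differences lying under the footprint
#' and an end-weighted score giving weight 2 to positions within the 5
#' terminal bases at either end of the oligo (where mismatches disrupt
#' annealing most) and 1 elsewhere.
#'
#' @param start,end 1-based footprint interval on the alignment.
#' @param aln a `barcode_aln`.
#' @param table a `sample_table`.
#' @param fixed optional precomputed fixed-difference positions.
#' @return list with `count`, `positions`, `end_weighted_score`.
#' @export
discriminative_support <- function(start, end, aln, table, fixed = NULL) {
  if (start < 1 || end > ncol(aln) || start > end)
    stop("footprint outside alignment")
  if (is.null(fixed)) fixed <- fixed_difference_positions(aln, table)
  pos <- fixed[fixed >= start & fixed <= end]
  w <- ifelse(pos - start < 5 | end - pos < 5, 2, 1)
  list(count = length(pos), positions = pos,
       end_weighted_score = sum(w))
}

#' Rank feasible forward/reverse/probe assay sets
#'
#' Feasible triples have forward, probe and reverse footprints in
#' left-to-right order without overlap, and probe NN Tm strictly above both
#' primer Tms. Triples are ranked lexicographically: total discriminative
#' count (descending), end-weighted discriminative score (descending), probe
#' minus mean-primer Tm differential (descending), aggregate structure
#' penalty (self-dimer Tms + hairpin + self-annealing of the three oligos
#' plus the forward/reverse hetero-dimer Tm, ascending); remaining ties break
#' on coordinates. The ordering is invariant to the input order of
#' candidates.
#'
#' @param candidates data.frame of candidates (rows from
#'   [enumerate_candidates()], any mix of roles).
#' @param constraints an [oligo_constraints()].
#' @param aln,table alignment and metadata for discriminative scoring.
#' @return data.frame of class `assay_sets`, one row per feasible triple with
#'   `rank`, oligo columns prefixed `fwd_`/`rev_`/`probe_`,
#'   `amplicon_start`, `amplicon_end`, `amplicon_length`,
#'   `total_discriminative`, `end_weighted`, `tm_differential`,
#'   `structure_penalty`. Empty with attribute `diagnostics` when no triple
#'   is feasible.
#' @export
rank_assay_sets <- function(candidates, constraints = oligo_constraints(),
                            aln, table) {
  f <- candidates[candidates$role == "forward", , drop = FALSE]
  r <- candidates[candidates$role == "reverse", , drop = FALSE]
  p <- candidates[candidates$role == "probe", , drop = FALSE]
  diag_msgs <- character(0)
  if (!nrow(f)) diag_msgs <- c(diag_msgs, "no forward candidates")
  if (!nrow(r)) diag_msgs <- c(diag_msgs, "no reverse candidates")
  if (!nrow(p)) diag_msgs <- c(diag_msgs, "no probe candidates")
  fixed <- fixed_difference_positions(aln, table)
  rows <- list()
  if (!length(diag_msgs)) {
    infeasible <- c(geometry = 0L, probe_tm = 0L)
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(p)))
      for (k in seq_len(nrow(r))) {
        fi <- f[i, ]; pj <- p[j, ]; rk <- r[k, ]
        if (!(fi$end < pj$start && pj$end < rk$start)) {
          infeasible["geometry"] <- infeasible["geometry"] + 1L
          next
        }
        if (!(pj$tm_nn > fi$tm_nn && pj$tm_nn > rk$tm_nn)) {
          infeasible["probe_tm"] <- infeasible["probe_tm"] + 1L
          next
        }
        ds <- lapply(list(fi, pj, rk), function(o)
          discriminative_support(o$start, o$end, aln, table, fixed))
        het <- structure_screen(fi$sequence, rk$sequence,
                                constraints$mono, constraints$div,
                                constraints$dntp,
                                constraints$ct)$hetero_dimer_tm
        pen <- fi$self_dimer_tm + rk$self_dimer_tm + pj$self_dimer_tm +
          fi$hairpin + rk$hairpin + pj$hairpin +
          fi$self_annealing + rk$self_annealing + pj$self_annealing + het
        rows[[length(rows) + 1]] <- data.frame(
          fwd_sequence = fi$sequence, fwd_start = fi$start,
          fwd_end = fi$end, fwd_tm = fi$tm_nn,
          rev_sequence = rk$sequence, rev_start = rk$start,
          rev_end = rk$end, rev_tm = rk$tm_nn,
          probe_sequence = pj$sequence, probe_start = pj$start,
          probe_end = pj$end, probe_tm = pj$tm_nn,
          amplicon_start = fi$start, amplicon_end = rk$end,
          amplicon_length = rk$end - fi$start + 1,
          total_discriminative = sum(vapply(ds, `[[`, 0, "count")),
          end_weighted = sum(vapply(ds, `[[`, 0, "end_weighted_score")),
          tm_differential = pj$tm_nn - mean(c(fi$tm_nn, rk$tm_nn)),
          structure_penalty = pen, stringsAsFactors = FALSE)
      }
  }
  if (!length(rows)) {
    out <- data.frame()
    attr(out, "diagnostics") <- if (length(diag_msgs)) diag_msgs else
      c("no feasible geometry/probe-Tm triple")
    class(out) <- c("assay_sets", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$total_discriminative, -out$end_weighted,
               -out$tm_differential, out$structure_penalty,
               out$fwd_start, out$probe_start, out$rev_start,
               out$fwd_end, out$probe_end, out$rev_end)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("assay_sets", "data.frame")
  out
}

#' Design a diagnostic assay end to end
#'
#' Scans for the best diagnostic segment, enumerates candidates for the
#' three roles on the target-group consensus windows, and ranks assay sets.
#'
#' @param aln a `barcode_aln`.
#' @param table a `sample_table`.
#' @param constraints an [oligo_constraints()].
#' @param segment_len,oligo_window,lambda passed to [snv_density_scan()].
#' @param n_segments number of top segments to try (default 3).
#' @return an `assay_sets` data.frame (best segment that yields a feasible
#'   set), with attribute `segment`.
#' @export
design_assay <- function(aln, table, constraints = oligo_constraints(),
                         segment_len = 125, oligo_window = 30, lambda = 1.0,
                         n_segments = 3) {
  wins <- snv_density_scan(aln, table, segment_len, oligo_window, lambda)
  if (!nrow(wins)) stop("no design window with positive score")
  tgt <- group_ids(as_sample_table(as.data.frame(table), aln), "target")
  cons <- consensus_sequence(aln, intersect(tgt, rownames(aln)))
  W <- attr(wins, "oligo_window")
  for (i in seq_len(min(n_segments, nrow(wins)))) {
    wrow <- wins[i, ]
    cands <- do.call(rbind, list(
      enumerate_candidates(substr(cons, wrow$fwd_start,
                                  wrow$fwd_start + W - 1),
                           constraints, "forward", wrow$fwd_start),
      enumerate_candidates(substr(cons, wrow$probe_start,
                                  wrow$probe_start + W - 1),
                           constraints, "probe", wrow$probe_start),
      enumerate_candidates(substr(cons, wrow$rev_start,
                                  wrow$rev_start + W - 1),
                           constraints, "reverse", wrow$rev_start)))
    sets <- rank_assay_sets(cands, constraints, aln, table)
    if (nrow(sets)) {
      attr(sets, "segment") <- c(start = wrow$segment_start,
                                 end = wrow$segment_end)
      return(sets)
    }
  }
  stop("no feasible assay set in the top ", n_segments, " segments")
}

#' Design a control assay in a conserved region
#'
#' Window selection is inverted relative to the diagnostic design: the
#' longest run of columns invariant across every sample (all groups) is
#' located, candidates are enumerated on the all-sample consensus inside it,
#' and the selected control oligos must each have NN Tm at or below the
#' corresponding diagnostic oligo's Tm (so the control never outcompetes the
#' diagnostic reaction). Among feasible triples the one with the highest
#' (still bounded) Tms is kept.
#'
#' @param aln a `barcode_aln`.
#' @param table a `sample_table`.
#' @param diagnostic a one-row `assay_sets` slice for the diagnostic assay.
#' @param constraints an [oligo_constraints()].
#' @return a one-row `assay_sets`-like data.frame for the control.
#' @export
design_control_assay <- function(aln, table, diagnostic,
                                 constraints = oligo_constraints()) {
  vc <- variable_columns(aln, rownames(aln))
  inv <- setdiff(seq_len(ncol(aln)), vc)
  if (!length(inv))
    stop("no fully conserved window; relax the conservation threshold ",
         "or supply a conserved-locus alignment")
  r <- rle(seq_len(ncol(aln)) %in% inv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  blocks <- data.frame(start = starts[r$values], end = ends[r$values])
  blocks$len <- blocks$end - blocks$start + 1
  blocks <- blocks[order(-blocks$len), , drop = FALSE]
  need <- 2 * constraints$primer_len["min"] + constraints$probe_len["min"]
  if (!nrow(blocks) || blocks$len[1] < need)
    stop("no fully conserved window long enough (need ", need,
         " nt); relax the conservation threshold")
  cons <- consensus_sequence(aln, rownames(aln))
  blk <- blocks[1, ]
  third <- floor(blk$len / 3)
  seg <- function(k) substr(cons, blk$start + (k - 1) * third,
                            if (k < 3) blk$start + k * third - 1 else blk$end)
  offs <- blk$start + (0:2) * third
  cap_tm <- c(forward = diagnostic$fwd_tm, probe = diagnostic$probe_tm,
              reverse = diagnostic$rev_tm)
  pick <- list()
  for (role in c("forward", "probe", "reverse")) {
    k <- switch(role, forward = 1, probe = 2, reverse = 3)
    # cap the enumeration's Tm range at the diagnostic oligo's Tm, so the
    # kept candidates are not truncated away above the cap
    cn2 <- constraints
    fld <- if (role == "probe") "probe_tm" else "primer_tm"
    v <- cn2[[fld]]
    v["max"] <- min(v["max"], cap_tm[[role]])
    if (v["min"] > v["max"])
      stop("diagnostic ", role, " Tm (", round(cap_tm[[role]], 1),
           ") is below the role's minimum acceptable Tm")
    v["opt"] <- min(v["opt"], v["max"])
    cn2[[fld]] <- v
    cands <- enumerate_candidates(seg(k), cn2, role, offs[k])
    cands <- cands[cands$tm_nn <= cap_tm[[role]], , drop = FALSE]
    if (!nrow(cands))
      stop("no ", role, " control candidate with Tm <= diagnostic ",
           role, " Tm")
    # highest Tm still at or below the diagnostic's
    cands <- cands[order(-cands$tm_nn, cands$start), , drop = FALSE]
    pick[[role]] <- cands[1, ]
  }
  fi <- pick$forward; pj <- pick$probe; rk <- pick$reverse
  data.frame(
    fwd_sequence = fi$sequence, fwd_start = fi$start, fwd_end = fi$end,
    fwd_tm = fi$tm_nn,
    rev_sequence = rk$sequence, rev_start = rk$start, rev_end = rk$end,
    rev_tm = rk$tm_nn,
    probe_sequence = pj$sequence, probe_start = pj$start,
    probe_end = pj$end, probe_tm = pj$tm_nn,
    amplicon_start = fi$start, amplicon_end = rk$end,
    amplicon_length = rk$end - fi$start + 1,
    total_discriminative = 0, end_weighted = 0,
    tm_differential = pj$tm_nn - mean(c(fi$tm_nn, rk$tm_nn)),
    structure_penalty = NA_real_, rank = 1L, stringsAsFactors = FALSE)
}

#' In-silico specificity of an assay against a sequence panel
#'
#' For each panel sample, mismatches are counted under each oligo footprint
#' on the top strand (a position matches when the sample's IUPAC code covers
#' the expected base; gaps mismatch). Amplification is predicted when each
#' primer has at most 2 total mismatches and none in its 3 terminal 3'-end
#' bases, and the probe has at most 1 mismatch. The forward primer's 3' end
#' is the right edge of its footprint; the reverse primer's is the left edge.
#'
#' @param assay a one-row assay-set slice.
#' @param panel a `barcode_aln` sharing the design coordinates.
#' @param max_primer_mm,max_probe_mm,three_prime_window tolerance rule
#'   parameters.
#' @return data.frame per sample: `sample_id`, `fwd_mm`, `fwd_3p_mm`,
#'   `rev_mm`, `rev_3p_mm`, `probe_mm`, `predicted_amplification`.
#' @export
in_silico_specificity <- function(assay, panel, max_primer_mm = 2,
                                  max_probe_mm = 1, three_prime_window = 3) {
  L <- ncol(panel)
  coords <- c(assay$fwd_start, assay$fwd_end, assay$rev_start, assay$rev_end,
              assay$probe_start, assay$probe_end)
  if (any(coords < 1) || any(coords > L))
    stop("oligo footprint outside panel coordinates")
  exp_fwd <- strsplit(assay$fwd_sequence, "")[[1]]
  exp_rev <- strsplit(reverse_complement(assay$rev_sequence), "")[[1]]
  exp_probe <- strsplit(assay$probe_sequence, "")[[1]]
  m <- unclass(panel)
  mism <- function(expected, start, row) {
    obs <- m[row, start:(start + length(expected) - 1)]
    vapply(seq_along(expected), function(t) {
      o <- obs[t]
      if (o == "-" || !(o %in% names(IUPAC_SETS))) return(TRUE)
      !(expected[t] %in% IUPAC_SETS[[o]])
    }, TRUE)
  }
  rows <- lapply(rownames(m), function(id) {
    fm <- mism(exp_fwd, assay$fwd_start, id)
    rm_ <- mism(exp_rev, assay$rev_start, id)
    pm <- mism(exp_probe, assay$probe_start, id)
    n_f <- length(fm); n_r <- length(rm_)
    f3 <- sum(fm[(n_f - three_prime_window + 1):n_f])
    r3 <- sum(rm_[1:three_prime_window])
    data.frame(sample_id = id, fwd_mm = sum(fm), fwd_3p_mm = f3,
               rev_mm = sum(rm_), rev_3p_mm = r3, probe_mm = sum(pm),
               predicted_amplification =
                 sum(fm) <= max_primer_mm && f3 == 0 &&
                 sum(rm_) <= max_primer_mm && r3 == 0 &&
                 sum(pm) <= max_probe_mm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
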