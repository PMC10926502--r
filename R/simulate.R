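# Seeded synthetic-data generators. The barcode generator plants a haplotype
# structure typical of a near-homogeneous pest lineage: one large central
# haplotype with a star of close satellites, a distant conspecific outlier
# lineage, a few more distant congeners, and one outgroup. Every mutation
# hits a fresh alignment column (no homoplasy), so planted step counts equal
# realized Hamming distances and all network/path metrics are fixed by
# construction. The qPCR generator draws wells from per-class models whose
# positives satisfy the default call thresholds by construction (a simulation
# convenience, not a biological claim).

#' Barcode simulation configuration
#'
#' Defaults: 420-nt alignment; a main haplogroup of one central haplotype
#' (60 members) plus 12 one-step and 1 two-step satellite haplotypes (1-5
#' members each, cycling), i.e. 14 distinct variable positions and a
#' group diameter of 3 steps; a conspecific outlier lineage of 2 members at
#' 20 steps from the center; three nontarget pseudo-species at 40/45/60
#' steps (2 members each); one outgroup at 80 steps. Four subspecies labels
#' are assigned round-robin across main-group members, deliberately
#' discordant with haplotype identity.
#'
#' @param L alignment length (nt).
#' @param center_members members of the central haplotype.
#' @param satellite_steps steps from the center per satellite haplotype.
#' @param satellite_members member counts per satellite (recycled).
#' @param outlier_steps,outlier_members the conspecific outlier lineage.
#' @param nontarget_steps steps from the center per nontarget species.
#' @param nontarget_members members per nontarget species.
#' @param outgroup_steps steps from the center for the single outgroup.
#' @param stem_steps number of main-group stem positions: derived states
#'   shared by every main-group member and carried by no other lineage (the
#'   target lineage's own apomorphies, the raw material of diagnostic
#'   design). Counted inside `outlier_steps`/`nontarget_steps`/
#'   `outgroup_steps`, so all planted separations from the main group are
#'   unchanged.
#' @param stem_spacing spacing (columns) between consecutive stem positions;
#'   clustering them emulates the locally high SNV density that makes a
#'   diagnostic window designable.
#' @param reserved_region 1-based column interval holding the stem and kept
#'   free of all other branch mutations, so design windows are clean of
#'   intra-target variation.
#' @param subspecies labels cycled over main-group members.
#' @param control_L length of the companion conserved control locus
#'   (rDNA-like; invariant across every ingroup sample, a few substitutions
#'   in the outgroup only), used for control-assay design.
#' @param control_outgroup_steps outgroup substitutions on the control
#'   locus.
#' @return list of class `barcode_sim_config`.
#' @export
barcode_sim_config <- function(L = 420, center_members = 60,
                               satellite_steps = c(rep(1, 12), 2),
                               satellite_members = 1:5,
                               outlier_steps = 20, outlier_members = 2,
                               nontarget_steps = c(40, 45, 60),
                               nontarget_members = 2,
                               outgroup_steps = 80,
                               stem_steps = 12, stem_spacing = 4,
                               reserved_region = c(150, 300),
                               subspecies = paste0("ssp_", 1:4),
                               control_L = 200,
                               control_outgroup_steps = 3) {
  if (stem_steps > 0) {
    stopifnot(outlier_steps > stem_steps,
              all(nontarget_steps > stem_steps),
              outgroup_steps > stem_steps,
              reserved_region[1] >= 1, reserved_region[2] <= L)
  }
  structure(list(L = L, center_members = center_members,
                 satellite_steps = satellite_steps,
                 satellite_members = satellite_members,
                 outlier_steps = outlier_steps,
                 outlier_members = outlier_members,
                 nontarget_steps = nontarget_steps,
                 nontarget_members = nontarget_members,
                 outgroup_steps = outgroup_steps,
                 stem_steps = stem_steps, stem_spacing = stem_spacing,
                 reserved_region = reserved_region,
                 subspecies = subspecies,
                 control_L = control_L,
                 control_outgroup_steps = control_outgroup_steps),
            class = "barcode_sim_config")
}

mutate_at <- function(seqvec, positions) {
  for (p in positions)
    seqvec[p] <- sample(setdiff(BASES, seqvec[p]), 1)
  seqvec
}

#' Generate a synthetic barcode dataset
#'
#' Draws a random ancestral sequence; the main-group center derives from it
#' at the clustered stem positions, and every branch then plants its
#' mutations on fresh, globally unique positions (mutated base uniform among
#' the three alternatives), so there is no homoplasy and Hamming distances
#' equal the summed planted steps along the true tree. Members of a
#' haplotype are identical strings. With `stem_steps = 0` the construction
#' degenerates to a pure star around the center. The same seed yields
#' byte-identical output.
#'
#' @param cfg a [barcode_sim_config()].
#' @param seed integer RNG seed.
#' @return list of class `barcode_sim`: `alignment` (a `barcode_aln`),
#'   `control_alignment` (the conserved companion locus), `table` (a
#'   `sample_table`), `truth` (per-sample `lineage` in
#'   main/outlier/nontarget/outgroup and haplotype branch),
#'   `branch_positions` (planted positions per branch).
#' @export
generate_barcode_dataset <- function(cfg = barcode_sim_config(), seed = 1) {
  stem <- cfg$stem_steps
  total_steps <- sum(cfg$satellite_steps) + cfg$outlier_steps +
    sum(cfg$nontarget_steps) + cfg$outgroup_steps
  if (total_steps > cfg$L)
    stop("planted steps (", total_steps, ") exceed alignment length ", cfg$L)
  set.seed(seed)
  anc <- sample(BASES, cfg$L, replace = TRUE)
  if (stem > 0) {
    stem_pos <- cfg$reserved_region[1] + 11 +
      cfg$stem_spacing * (seq_len(stem) - 1)
    if (max(stem_pos) > cfg$reserved_region[2])
      stop("stem does not fit in reserved_region")
    free_cols <- setdiff(seq_len(cfg$L),
                         cfg$reserved_region[1]:cfg$reserved_region[2])
  } else {
    stem_pos <- integer(0)
    free_cols <- seq_len(cfg$L)
  }
  pool <- sample(free_cols)  # fresh positions, globally without replacement
  take <- function(k) {
    if (k == 0) return(integer(0))
    if (k > length(pool)) stop("planted steps exceed available columns")
    out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out
  }
  # the main-group center carries the stem-derived states; every other
  # lineage branches from the ancestral sequence
  center <- mutate_at(anc, stem_pos)
  haps <- list(main_center = center)
  branch_pos <- list(main_center = stem_pos)
  nsat <- length(cfg$satellite_steps)
  for (i in seq_len(nsat)) {
    ps <- take(cfg$satellite_steps[i])
    haps[[paste0("main_sat", i)]] <- mutate_at(center, ps)
    branch_pos[[paste0("main_sat", i)]] <- ps
  }
  if (cfg$outlier_members > 0) {
    ps <- take(cfg$outlier_steps - stem)
    haps[["outlier"]] <- mutate_at(anc, ps)
    branch_pos[["outlier"]] <- ps
  }
  for (i in seq_along(cfg$nontarget_steps)) {
    ps <- take(cfg$nontarget_steps[i] - stem)
    haps[[paste0("nontarget", i)]] <- mutate_at(anc, ps)
    branch_pos[[paste0("nontarget", i)]] <- ps
  }
  ps <- take(cfg$outgroup_steps - stem)
  haps[["outgroup"]] <- mutate_at(anc, ps)
  branch_pos[["outgroup"]] <- ps

  sat_members <- rep_len(cfg$satellite_members, nsat)
  mk_ids <- function(prefix, n) sprintf("%s_%02d", prefix, seq_len(n))
  seqs <- character(0); meta <- list()
  add <- function(hap_name, ids, species, subspecies, group, locality,
                  lineage) {
    s <- stats::setNames(rep(paste(haps[[hap_name]], collapse = ""),
                             length(ids)), ids)
    seqs <<- c(seqs, s)
    meta[[length(meta) + 1]] <<- data.frame(
      sample_id = ids, species = species, subspecies = subspecies,
      group = group, locality = locality, source = "simulated",
      lineage = lineage, haplotype_branch = hap_name,
      stringsAsFactors = FALSE)
  }
  add("main_center", mk_ids("tgt_c", cfg$center_members), "D_target", "",
      "target", "range_core", "main")
  for (i in seq_len(nsat))
    add(paste0("main_sat", i), mk_ids(sprintf("tgt_s%02d", i),
                                      sat_members[i]),
        "D_target", "", "target", "range_core", "main")
  if (cfg$outlier_members > 0)
    add("outlier", mk_ids("tgt_wc", cfg$outlier_members), "D_target", "",
        "target", "western_outlier", "outlier")
  for (i in seq_along(cfg$nontarget_steps))
    add(paste0("nontarget", i),
        mk_ids(sprintf("non%d", i), cfg$nontarget_members),
        sprintf("D_near_%d", i), "", "nontarget", "congener_range",
        "nontarget")
  add("outgroup", "outg_01", "outgroup_sp", "", "outgroup", "distant",
      "outgroup")
  tab <- do.call(rbind, meta)
  # subspecies round-robin over main-group members, discordant with haplotype
  main_rows <- which(tab$lineage == "main")
  tab$subspecies[main_rows] <-
    rep_len(cfg$subspecies, length(main_rows))
  aln <- as_alignment(seqs)
  truth <- tab[, c("sample_id", "lineage", "haplotype_branch")]
  table <- as_sample_table(tab[, SAMPLE_COLS], aln)
  # companion conserved control locus: identical across the ingroup, a few
  # outgroup-only substitutions
  ctrl_base <- sample(BASES, cfg$control_L, replace = TRUE)
  ctrl_out <- mutate_at(ctrl_base,
                        sample.int(cfg$control_L,
                                   cfg$control_outgroup_steps))
  ctrl_seqs <- vapply(tab$sample_id, function(id) {
    v <- if (tab$group[tab$sample_id == id] == "outgroup") ctrl_out else
      ctrl_base
    paste(v, collapse = "")
  }, "")
  control_aln <- as_alignment(ctrl_seqs)
  structure(list(alignment = aln, control_alignment = control_aln,
                 table = table, truth = truth,
                 branch_positions = branch_pos, config = cfg, seed = seed),
            class = "barcode_sim")
}

#' qPCR simulation configuration
#'
#' Class models (defaults in parentheses): positives draw diagnostic Cq from
#' Normal(15.71, 4.38) truncated to the positive window, control Cq as
#' diagnostic plus a signed Normal(1.50, 0.65) magnitude (redrawn until both
#' Cqs sit in the window and delta-Cq is within the cutoff), and end RFUs
#' from Normal(1359.33, 209.07) / Normal(1533.68, 546.79) floored just above
#' the channel thresholds; anomalous wells draw diagnostic Cq uniformly
#' below the window (range 1.6-5.6 truncated at the window floor) and
#' control Cq uniformly above it (32.9-37.1); negatives have no diagnostic
#' amplification; failures have none on either channel.
#'
#' @param n_positive,n_anomalous,n_negative,n_failed per-class sample counts
#'   (defaults 110/4/3/1).
#' @param diag_cq,ctrl_cq,delta,diag_rfu,ctrl_rfu `c(mean, sd)` pairs
#'   (`ctrl_cq` is used for the control channel of non-positive classes).
#' @param anom_diag,anom_ctrl uniform ranges for the anomalous class.
#' @param thresholds a [call_thresholds()] the positives must satisfy.
#' @return list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(n_positive = 110, n_anomalous = 4,
                            n_negative = 3, n_failed = 1,
                            diag_cq = c(15.71, 4.38),
                            ctrl_cq = c(17.18, 3.99),
                            delta = c(1.50, 0.65),
                            diag_rfu = c(1359.33, 209.07),
                            ctrl_rfu = c(1533.68, 546.79),
                            anom_diag = c(1.6, 5.6),
                            anom_ctrl = c(32.9, 37.1),
                            thresholds = call_thresholds()) {
  stopifnot(n_positive >= 0, n_anomalous >= 0, n_negative >= 0,
            n_failed >= 0)
  structure(list(n_positive = n_positive, n_anomalous = n_anomalous,
                 n_negative = n_negative, n_failed = n_failed,
                 diag_cq = diag_cq, ctrl_cq = ctrl_cq,
                 delta = delta, diag_rfu = diag_rfu,
                 ctrl_rfu = ctrl_rfu, anom_diag = anom_diag,
                 anom_ctrl = anom_ctrl, thresholds = thresholds),
            class = "qpcr_sim_config")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) { out[i] <- x; break }
    }
  }
  out
}

#' Generate a synthetic qPCR run
#'
#' @param cfg a [qpcr_sim_config()].
#' @param seed integer RNG seed.
#' @return list of class `qpcr_sim`: `wells` (data.frame `sample_id`,
#'   `channel`, `cq`, `end_rfu`), `truth` (data.frame `sample_id`, `class`).
#' @export
generate_qpcr_run <- function(cfg = qpcr_sim_config(), seed = 1) {
  set.seed(seed)
  t <- cfg$thresholds
  rows <- list(); truth <- list()
  add_sample <- function(id, class, dcq, drfu, ccq, crfu) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = id, channel = c("diagnostic", "control"),
      cq = c(dcq, ccq), end_rfu = c(drfu, crfu), stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <<- data.frame(sample_id = id, class = class,
                                              stringsAsFactors = FALSE)
  }
  bg_rfu <- function() stats::runif(1, 0, 100)
  for (i in seq_len(cfg$n_positive)) {
    repeat {
      dcq <- rnorm_trunc(1, cfg$diag_cq[1], cfg$diag_cq[2], t$cq_min,
                         t$cq_max)
      dl <- abs(stats::rnorm(1, cfg$delta[1], cfg$delta[2])) *
        sample(c(-1, 1), 1)
      ccq <- dcq + dl
      if (ccq >= t$cq_min && ccq <= t$cq_max && abs(dl) <= t$delta_max)
        break
    }
    drfu <- max(stats::rnorm(1, cfg$diag_rfu[1], cfg$diag_rfu[2]),
                t$rfu_diag + 1)
    crfu <- max(stats::rnorm(1, cfg$ctrl_rfu[1], cfg$ctrl_rfu[2]),
                t$rfu_ctrl + 1)
    add_sample(sprintf("pos_%03d", i), "positive", dcq, drfu, ccq, crfu)
  }
  for (i in seq_len(cfg$n_anomalous)) {
    dcq <- stats::runif(1, cfg$anom_diag[1],
                        min(cfg$anom_diag[2], t$cq_min - 1e-6))
    ccq <- stats::runif(1, max(cfg$anom_ctrl[1], t$cq_max + 1e-6),
                        cfg$anom_ctrl[2])
    drfu <- max(stats::rnorm(1, cfg$diag_rfu[1], cfg$diag_rfu[2]), 0)
    crfu <- bg_rfu()
    add_sample(sprintf("anom_%03d", i), "anomalous", dcq, drfu, ccq, crfu)
  }
  for (i in seq_len(cfg$n_negative)) {
    ccq <- rnorm_trunc(1, cfg$ctrl_cq[1], cfg$ctrl_cq[2],
                       t$cq_min, t$cq_max)
    crfu <- max(stats::rnorm(1, cfg$ctrl_rfu[1], cfg$ctrl_rfu[2]),
                t$rfu_ctrl + 1)
    add_sample(sprintf("neg_%03d", i), "negative", NA_real_, bg_rfu(),
               ccq, crfu)
  }
  for (i in seq_len(cfg$n_failed))
    add_sample(sprintf("fail_%03d", i), "failed", NA_real_, bg_rfu(),
               NA_real_, bg_rfu())
  wells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), channel = character(),
               cq = numeric(), end_rfu = numeric())
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample_id = character(), class = character())
  structure(list(wells = wells, truth = truth, config = cfg, seed = seed),
            class = "qpcr_sim")
}

#' Write the synthetic barcode dataset to FASTA/TSV
#' @param sim a `barcode_sim`.
#' @param fasta,tsv output paths.
#' @export
write_barcode_sim <- function(sim, fasta, tsv) {
  write_alignment(sim$alignment, fasta)
  utils::write.table(as.data.frame(sim$table), tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(sim)
}
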