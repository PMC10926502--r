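# End-to-end convenience wrapper tying the stages together on the synthetic
# dataset: simulate -> trim -> haplotypes -> network -> design ->
# control design -> specificity -> simulated qPCR run -> calls.

#' Run the full synthetic pipeline
#'
#' Generates a barcode dataset, trims it, collapses haplotypes, builds the
#' statistical-parsimony network and its path metrics, designs the
#' diagnostic assay (with the conspecific outlier lineage excluded from the
#' design target, mirroring an assay scoped to the main haplogroup), designs
#' the control assay, screens specificity in silico against the full panel,
#' then simulates a qPCR run and classifies it.
#'
#' @param seed integer seed driving both generators.
#' @param barcode_cfg a [barcode_sim_config()].
#' @param qpcr_cfg a [qpcr_sim_config()].
#' @param constraints an [oligo_constraints()].
#' @return list with elements `sim`, `alignment`, `table`, `haplotypes`,
#'   `network`, `metrics`, `assay`, `control`, `specificity`, `qpcr`,
#'   `calls`, `summary`.
#' @export
run_pipeline <- function(seed = 1, barcode_cfg = barcode_sim_config(),
                         qpcr_cfg = qpcr_sim_config(),
                         constraints = oligo_constraints()) {
  sim <- generate_barcode_dataset(barcode_cfg, seed)
  aln <- trim_to_core(sim$alignment)
  haps <- collapse_haplotypes(aln)
  limit <- parsimony_connection_limit(ncol(aln))
  net <- build_network(haps, limit, force_connect = TRUE)
  hap_of <- function(ids) unique(names(Filter(
    function(mem) any(mem %in% ids), net$haplotypes$membership)))
  lineages <- split(sim$truth$sample_id, sim$truth$lineage)
  subgroups <- lapply(lineages, hap_of)
  metrics <- path_metrics(net, subgroups)
  # design against the main haplogroup only: the outlier lineage is moved to
  # the nontarget side so the assay may exclude it
  design_table <- as.data.frame(sim$table)
  outlier_ids <- sim$truth$sample_id[sim$truth$lineage == "outlier"]
  design_table$group[design_table$sample_id %in% outlier_ids] <- "nontarget"
  design_table <- as_sample_table(design_table, aln)
  assay <- design_assay(aln, design_table, constraints)
  control <- design_control_assay(sim$control_alignment, design_table,
                                  assay[1, ], constraints)
  spec <- in_silico_specificity(assay[1, ], aln)
  qpcr <- generate_qpcr_run(qpcr_cfg, seed)
  calls <- classify_run(qpcr$wells, qpcr_cfg$thresholds)
  list(sim = sim, alignment = aln, table = design_table, haplotypes = haps,
       network = net, metrics = metrics, assay = assay, control = control,
       specificity = spec, qpcr = qpcr, calls = calls,
       summary = summarize_run(calls, qpcr$wells))
}
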