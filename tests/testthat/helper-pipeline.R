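# Builds a complete on-disk input set for run_pipeline() from the default
# synthetic scenario: alignment, nonconserved model, outgroup and feature
# tracks, plus the matching config list.
make_pipeline_inputs <- function(dir, seed = 42L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_alignment(seed = seed)
  write_alignment(sim$alignment, file.path(dir, "aln.fasta"))
  write_mod(default_model(), file.path(dir, "noncons.mod"))
  # the root sequence stands in for a related repeat unit as outgroup
  write_fasta(c(outgroup = sim$truth$root_sequence),
              file.path(dir, "outgroup.fasta"))
  tracks <- simulate_feature_tracks(sim$truth, seed = seed,
                                    seqname = "human")
  track_cfg <- list()
  for (k in seq_along(tracks)) {
    p <- file.path(dir, sprintf("track%02d.bed", k))
    write_bed(tracks[[k]]$intervals, p)
    track_cfg[[k]] <- list(path = p, dialect = "BED",
                           feature_type = tracks[[k]]$feature_type,
                           cell_line = tracks[[k]]$cell_line)
  }
  list(config = list(
    inputs = list(msa = file.path(dir, "aln.fasta"),
                  reference_id = "human",
                  noncons_mod = file.path(dir, "noncons.mod"),
                  outgroup_fasta = file.path(dir, "outgroup.fasta"),
                  tracks = track_cfg,
                  span = list(start = 0L, end = 5000L)),
    outdir = file.path(dir, "out"),
    seed = seed),
    truth = sim$truth)
}
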