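# End-to-end wiring: phase -> compare -> refine -> diagnose -> report.

#' Reconstruct refined haplotype blocks for every embryo
#'
#' Phases the reference child and each embryo against the parents, builds the
#' paternal and maternal observation tracks versus the reference, and refines
#' each track with the HMM.
#'
#' @param gm A `genotype_matrix`.
#' @param params [hmm_parameters()].
#' @return List with `ref_hap`, `embryo_haps` (named list), `tracks` and
#'   `segmentations` (named list per embryo of named list per origin).
#' @export
reconstruct_haplotypes <- function(gm, params = hmm_parameters()) {
  ref_id <- sample_by_role(gm, "reference_child")
  embryo_ids <- sample_by_role(gm, "embryo")
  ref_hap <- phase_sample(gm, ref_id)
  embryo_haps <- lapply(stats::setNames(nm = embryo_ids),
                        function(id) phase_sample(gm, id))
  tracks <- lapply(embryo_haps, function(h) {
    lapply(stats::setNames(nm = c("paternal", "maternal")), function(or) {
      build_observation_track(h, ref_hap, or)
    })
  })
  segmentations <- lapply(tracks, function(tr) {
    lapply(tr, function(t) {
      if (nrow(t) == 0L) NULL else refine_track(t, params)
    })
  })
  list(ref_hap = ref_hap, embryo_haps = embryo_haps,
       tracks = tracks, segmentations = segmentations)
}

#' Diagnose a whole family
#'
#' Full pipeline on an in-memory genotype matrix: haplotype reconstruction for
#' every embryo, per-origin carrier calls at the disease locus, and the family
#' summary.
#'
#' @param gm A `genotype_matrix`.
#' @param locus A [disease_locus()].
#' @param params [hmm_parameters()].
#' @return A `family_diagnosis` list: `reports`, `summary`, plus the
#'   intermediate `reconstruction`.
#' @export
diagnose_family <- function(gm, locus, params = hmm_parameters()) {
  rec <- reconstruct_haplotypes(gm, params)
  reports <- lapply(names(rec$segmentations), function(id) {
    segs <- rec$segmentations[[id]]
    segs <- segs[!vapply(segs, is.null, logical(1))]
    if (length(segs) == 0L) {
      structure(list(embryo_id = id,
                     origins = lapply(
                       stats::setNames(nm = locus$transmitting_parents),
                       function(or) list(call = "no_call_insufficient_data",
                                         state_at_locus = NA_character_,
                                         mean_posterior = NA_real_,
                                         n_sites_window = 0L)),
                     overall_status = "no_call"),
                class = "diagnosis_report")
    } else {
      diagnose_embryo(segs, locus, params)
    }
  })
  structure(list(reports = reports,
                 summary = summarize_family(reports),
                 reconstruction = rec,
                 locus = locus,
                 params = params),
            class = "family_diagnosis")
}

#' @export
print.family_diagnosis <- function(x, ...) {
  cat("family_diagnosis:", x$summary$n_embryos, "embryo(s) at",
      sprintf("%s:%s-%s (%s)\n", x$locus$chrom,
              format(x$locus$start_pos, scientific = FALSE, trim = TRUE),
              format(x$locus$end_pos, scientific = FALSE, trim = TRUE),
              x$locus$mode))
  for (e in x$summary$embryos) {
    calls <- vapply(e$origins, `[[`, character(1), "call")
    cat(sprintf("  %s: %s  [%s]\n", e$embryo_id, e$overall_status,
                paste(sprintf("%s=%s", names(e$origins), calls),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Run the full pipeline and persist every output
#'
#' Reads the VCF, diagnoses the family, and writes the phase table,
#' per-embryo/origin track and block TSVs, the diagnosis JSON, the SVG figures
#' and a run manifest into `outdir`.
#'
#' @param vcf_path Input VCF.
#' @param role_map Named character vector, sample id -> role.
#' @param locus A [disease_locus()].
#' @param params [hmm_parameters()].
#' @param outdir Output directory (created if absent).
#' @return The `family_diagnosis`, invisibly; side effect: files in `outdir`.
#' @export
run_pipeline <- function(vcf_path, role_map, locus,
                         params = hmm_parameters(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gm <- read_vcf(vcf_path, role_map)
  fd <- diagnose_family(gm, locus, params)
  rec <- fd$reconstruction

  write_phase_table(c(list(rec$ref_hap), unname(rec$embryo_haps)),
                    file.path(outdir, "phase_table.tsv"))
  for (id in names(rec$segmentations)) {
    for (or in names(rec$segmentations[[id]])) {
      seg <- rec$segmentations[[id]][[or]]
      if (is.null(seg)) next
      write_track_tsv(seg, file.path(outdir,
                                     sprintf("track_%s_%s.tsv", id, or)))
      write_blocks_tsv(seg, file.path(outdir,
                                      sprintf("blocks_%s_%s.tsv", id, or)))
    }
  }
  write_diagnosis_json(fd$summary, file.path(outdir, "diagnosis.json"))

  segs_flat <- lapply(rec$segmentations, function(s) {
    s[!vapply(s, is.null, logical(1))]
  })
  render_family_svg(segs_flat, locus,
                    file.path(outdir, "haplotype_blocks.svg"))

  manifest <- list(
    package = "embryohap",
    version = as.character(utils::packageVersion("embryohap")),
    input_vcf = basename(vcf_path),
    role_map = as.list(role_map),
    locus = unclass(locus),
    params = unclass(params),
    n_sites = nrow(gm$sites))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(fd)
}
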