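# Per-site comparison of an embryo's raw parental haplotype with the phased
# reference child: "i" where the origin allele is identical, "d" where it
# differs, NA where either side is unresolved. This observation track is the
# HMM input.

#' Build an i/d observation track
#'
#' Restricts to sites informative for the requested parental origin
#' (mother het / father hom for `"maternal"`, and vice versa) and compares the
#' embryo's origin allele with the reference child's.
#'
#' @param embryo_hap,ref_hap `phased_haplotype` objects on the same site
#'   index.
#' @param origin `"paternal"` or `"maternal"`.
#' @return An `observation_track`: data.frame(`chrom`, `pos`, `obs`) in
#'   genomic order, `obs` in `"i"`, `"d"` or NA (missing), with attributes
#'   `embryo_id` and `origin`.
#' @export
build_observation_track <- function(embryo_hap, ref_hap,
                                    origin = c("paternal", "maternal")) {
  origin <- match.arg(origin)
  if (!identical(embryo_hap$pos, ref_hap$pos) ||
      !identical(embryo_hap$chrom, ref_hap$chrom)) {
    stop("embryo and reference haplotypes are not on the same site index")
  }
  keep <- embryo_hap$site_class == paste0(origin, "_informative")
  e <- embryo_hap[keep, , drop = FALSE]
  r <- ref_hap[keep, , drop = FALSE]
  col <- if (origin == "paternal") "pat" else "mat"
  ea <- ifelse(e$flag == "ok", e[[col]], NA)
  ra <- ifelse(r$flag == "ok", r[[col]], NA)
  obs <- rep(NA_character_, nrow(e))
  both <- !is.na(ea) & !is.na(ra)
  obs[both] <- ifelse(ea[both] == ra[both], "i", "d")
  if (nrow(e) == 0L) {
    warning("no informative sites for origin ", origin,
            "; diagnosis will be a no-call")
  }
  out <- data.frame(chrom = e$chrom, pos = e$pos, obs = obs,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            embryo_id = attr(embryo_hap, "sample_id"),
            origin = origin,
            class = c("observation_track", "data.frame"))
}
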