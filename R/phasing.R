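# Mendelian trio phasing (step 1 of the method).
#
# At sites where one parent is heterozygous and the other homozygous
# ("informative" sites), the child's alleles can be assigned to a parental
# origin by the laws of segregation: the homozygous parent can only have
# transmitted its single allele, so the remaining child allele must come from
# the heterozygous parent. Genotypes are dosage codes (0/1/2/NA).

SITE_CLASSES <- c("paternal_informative", "maternal_informative",
                  "double_het", "uninformative")

#' Classify a site by parental informativeness
#'
#' @param father_gt,mother_gt Parental genotype dosage codes (0 = hom ref,
#'   1 = het, 2 = hom alt). Vectorized; must be non-missing.
#' @return Character vector: `"paternal_informative"` (father het, mother
#'   hom), `"maternal_informative"` (mother het, father hom), `"double_het"`,
#'   or `"uninformative"` (both hom).
#' @export
classify_site <- function(father_gt, mother_gt) {
  if (anyNA(father_gt) || anyNA(mother_gt)) {
    stop("missing parental genotype: parent-missing sites must be filtered first")
  }
  f_het <- father_gt == 1L
  m_het <- mother_gt == 1L
  out <- rep("uninformative", length(father_gt))
  out[f_het & !m_het] <- "paternal_informative"
  out[m_het & !f_het] <- "maternal_informative"
  out[f_het & m_het] <- "double_het"
  out
}

# All Mendelian-consistent (paternal, maternal) ordered allele assignments
# for one trio of dosage codes. Alleles are "ref"/"alt".
alleles_of <- function(code) {
  switch(as.character(code),
         "0" = "ref",
         "1" = c("ref", "alt"),
         "2" = "alt")
}

consistent_assignments <- function(f, m, c) {
  child <- sort(switch(as.character(c),
                       "0" = c("ref", "ref"),
                       "1" = c("alt", "ref"),
                       "2" = c("alt", "alt")))
  out <- list()
  for (p in alleles_of(f)) {
    for (mt in alleles_of(m)) {
      if (identical(sort(c(p, mt)), child)) {
        out[[length(out) + 1L]] <- c(pat = p, mat = mt)
      }
    }
  }
  unique(out)
}

# Lookup table over the 27 (father, mother, child) dosage combinations.
build_phase_table <- function() {
  pat <- mat <- flag <- array(NA_character_, dim = c(3, 3, 3))
  for (f in 0:2) for (m in 0:2) for (c in 0:2) {
    asn <- consistent_assignments(f, m, c)
    idx <- c(f, m, c) + 1L
    if (length(asn) == 0L) {
      flag[idx[1], idx[2], idx[3]] <- "mendelian_error"
    } else if (length(asn) == 1L) {
      flag[idx[1], idx[2], idx[3]] <- "ok"
      pat[idx[1], idx[2], idx[3]] <- asn[[1]]["pat"]
      mat[idx[1], idx[2], idx[3]] <- asn[[1]]["mat"]
    } else {
      flag[idx[1], idx[2], idx[3]] <- "unphaseable"
    }
  }
  list(pat = pat, mat = mat, flag = flag)
}

.phase_table <- build_phase_table()

#' Phase one trio site by Mendelian segregation
#'
#' Assigns the child's alleles to paternal and maternal origin where the
#' assignment is unique under Mendelian segregation. Double-heterozygous sites
#' with a heterozygous child are `unphaseable`; a child genotype impossible
#' given the parents is a `mendelian_error`; a missing child genotype is
#' `missing`.
#'
#' @param father_gt,mother_gt,child_gt Genotype dosage codes (vectorized).
#' @param site_class Optional precomputed [classify_site()] output (unused by
#'   the lookup itself; accepted for interface symmetry and checked for
#'   consistency when supplied).
#' @return data.frame with columns `pat`, `mat` (each `"ref"`, `"alt"` or NA)
#'   and `flag` (`"ok"`, `"unphaseable"`, `"mendelian_error"`, `"missing"`).
#' @export
phase_trio_site <- function(father_gt, mother_gt, child_gt, site_class = NULL) {
  if (anyNA(father_gt) || anyNA(mother_gt)) {
    stop("missing parental genotype: parent-missing sites must be filtered first")
  }
  if (!is.null(site_class)) {
    stopifnot(identical(site_class, classify_site(father_gt, mother_gt)))
  }
  n <- max(length(father_gt), length(mother_gt), length(child_gt))
  f <- rep_len(as.integer(father_gt), n)
  m <- rep_len(as.integer(mother_gt), n)
  c <- rep_len(as.integer(child_gt), n)
  pat <- mat <- rep(NA_character_, n)
  flag <- rep("missing", n)
  known <- !is.na(c)
  idx <- cbind(f[known] + 1L, m[known] + 1L, c[known] + 1L)
  pat[known] <- .phase_table$pat[idx]
  mat[known] <- .phase_table$mat[idx]
  flag[known] <- .phase_table$flag[idx]
  data.frame(pat = pat, mat = mat, flag = flag, stringsAsFactors = FALSE)
}

#' Phase the reference child or an embryo against the parents
#'
#' Applies [phase_trio_site()] at every retained site of the genotype matrix,
#' producing the sample's raw paternal/maternal haplotype.
#'
#' @param gm A `genotype_matrix`.
#' @param sample_id Sample to phase; must have role `reference_child` or
#'   `embryo`.
#' @return A `phased_haplotype`: data.frame with site columns (`chrom`, `pos`,
#'   `site_id`, `ref`, `alt`, `site_class`) plus `pat`, `mat`, `flag`; the
#'   sample id is kept in the `"sample_id"` attribute.
#' @export
phase_sample <- function(gm, sample_id) {
  role <- gm$samples$role[match(sample_id, gm$samples$sample_id)]
  if (is.na(role)) stop("unknown sample: ", sample_id)
  if (!role %in% c("reference_child", "embryo")) {
    stop("phase_sample applies to the reference child or an embryo, not ", role)
  }
  f <- gm$gt[, sample_by_role(gm, "father")]
  m <- gm$gt[, sample_by_role(gm, "mother")]
  c <- gm$gt[, sample_id]
  ph <- phase_trio_site(f, m, c)
  out <- cbind(gm$sites,
               data.frame(site_class = classify_site(f, m),
                          stringsAsFactors = FALSE),
               ph)
  rownames(out) <- NULL
  structure(out, sample_id = sample_id, role = role,
            class = c("phased_haplotype", "data.frame"))
}
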