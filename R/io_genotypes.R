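# Genotype I/O: multi-sample VCF ingestion, role assignment, site filtering,
# and the tabular outputs shared by the rest of the pipeline.
#
# Genotypes are stored as alt-allele dosage codes: 0 = hom ref, 1 = het,
# 2 = hom alt, NA = missing. Any phase separator in the input ("|") is
# accepted but ignored: phase is recomputed from the pedigree.

ROLE_LEVELS <- c("father", "mother", "reference_child", "embryo")

#' Validate a sample-to-role map
#'
#' @param role_map Named character vector mapping sample id to role. Roles are
#'   `"father"`, `"mother"`, `"reference_child"`, `"embryo"`. Exactly one of
#'   each parental role and the reference child is required, plus at least one
#'   embryo.
#' @return The validated map (invisibly usable), with names preserved.
#' @export
validate_role_map <- function(role_map) {
  if (is.null(names(role_map)) || any(!nzchar(names(role_map)))) {
    stop("role_map must be a named character vector (sample id -> role)")
  }
  bad <- setdiff(unique(role_map), ROLE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names(role_map))) {
    stop("duplicated sample ids in role_map")
  }
  for (r in c("father", "mother", "reference_child")) {
    if (sum(role_map == r) != 1L) {
      stop("role_map must contain exactly one ", r)
    }
  }
  if (sum(role_map == "embryo") < 1L) {
    stop("role_map must contain at least one embryo")
  }
  role_map
}

new_genotype_matrix <- function(sites, samples, gt) {
  stopifnot(nrow(sites) == nrow(gt), nrow(samples) == ncol(gt))
  rownames(gt) <- sites$site_id
  colnames(gt) <- samples$sample_id
  structure(list(sites = sites, samples = samples, gt = gt),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x", nrow(x$samples),
      "samples (", paste(unique(x$sites$chrom), collapse = ", "), ")\n")
  cat("roles:", paste(sprintf("%s=%s", x$samples$sample_id, x$samples$role),
                      collapse = ", "), "\n")
  invisible(x)
}

sample_by_role <- function(gm, role) {
  gm$samples$sample_id[gm$samples$role == role]
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads a VCF 4.x file (plain or bgzipped) with a GT FORMAT field, keeps the
#' samples named in `role_map`, decodes genotypes to dosage codes, sorts sites
#' by chromosome and position, and (by default) applies [filter_sites()] with
#' its defaults.
#'
#' @param path Path to the VCF file.
#' @param role_map Named character vector, sample id -> role
#'   (see [validate_role_map()]).
#' @param filter Apply [filter_sites()] defaults after loading. Default TRUE.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, role_map, filter = TRUE) {
  role_map <- validate_role_map(role_map)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  missing_samples <- setdiff(names(role_map), colnames(gt_raw))
  if (length(missing_samples) > 0) {
    stop("sample(s) named in role_map absent from VCF header: ",
         paste(missing_samples, collapse = ", "))
  }
  gt_raw <- gt_raw[, names(role_map), drop = FALSE]

  n <- nrow(fix)
  gt <- matrix(NA_integer_, nrow = n, ncol = ncol(gt_raw))
  non_diploid <- rep(FALSE, n)
  for (j in seq_len(ncol(gt_raw))) {
    alleles <- strsplit(gt_raw[, j], "[/|]")
    len2 <- lengths(alleles) == 2L
    non_diploid <- non_diploid | (!len2 & !is.na(gt_raw[, j]))
    a <- matrix(NA_character_, nrow = n, ncol = 2)
    a[len2, ] <- matrix(unlist(alleles[len2]), ncol = 2, byrow = TRUE)
    a[a == "."] <- NA
    ai <- suppressWarnings(matrix(as.integer(a), ncol = 2))
    gt[, j] <- ai[, 1] + ai[, 2]
    # allele index > 1 means a multi-allelic call; mark site for removal
    non_diploid <- non_diploid | (!is.na(ai[, 1]) & ai[, 1] > 1) |
      (!is.na(ai[, 2]) & ai[, 2] > 1)
  }
  if (any(non_diploid)) {
    warning(sum(non_diploid),
            " site(s) with non-diploid or multi-allelic GT calls skipped")
  }

  site_id <- fix$ID
  site_id[is.na(site_id) | site_id == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(site_id) | site_id == "."]
  sites <- data.frame(chrom = fix$CHROM,
                      pos = as.integer(fix$POS),
                      site_id = site_id,
                      ref = fix$REF,
                      alt = fix$ALT,
                      stringsAsFactors = FALSE)
  keep <- !non_diploid
  sites <- sites[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(sites) <- NULL

  samples <- data.frame(sample_id = names(role_map),
                        role = unname(role_map),
                        stringsAsFactors = FALSE)
  gm <- new_genotype_matrix(sites, samples, gt)
  if (filter) gm <- filter_sites(gm) else gm
}

#' Filter sites of a genotype matrix
#'
#' Removes multi-allelic records, non-SNP records (indels), and sites where a
#' parental genotype is missing: the parents are bulk DNA and must be callable
#' for Mendelian phasing. Embryo missingness is retained and handled
#' downstream as missing observations.
#'
#' @param gm A `genotype_matrix`.
#' @param max_parent_missing Maximum tolerated fraction of missing parental
#'   genotypes per site (of the two parents). Default 0.
#' @param biallelic_only Drop multi-allelic and non-SNP records. Default TRUE.
#' @return A `genotype_matrix` containing a subset of the input sites, order
#'   preserved.
#' @export
filter_sites <- function(gm, max_parent_missing = 0, biallelic_only = TRUE) {
  keep <- rep(TRUE, nrow(gm$sites))
  if (biallelic_only) {
    snp <- nchar(gm$sites$ref) == 1L & nchar(gm$sites$alt) == 1L &
      !grepl(",", gm$sites$alt, fixed = TRUE) &
      gm$sites$ref != gm$sites$alt &
      gm$sites$ref %in% c("A", "C", "G", "T") &
      gm$sites$alt %in% c("A", "C", "G", "T")
    keep <- keep & snp
  }
  parents <- c(sample_by_role(gm, "father"), sample_by_role(gm, "mother"))
  pmiss <- rowMeans(is.na(gm$gt[, parents, drop = FALSE]))
  keep <- keep & (pmiss <= max_parent_missing)
  if (!any(keep)) stop("no usable sites after filtering")
  new_genotype_matrix(gm$sites[keep, , drop = FALSE], gm$samples,
                      gm$gt[keep, , drop = FALSE])
}

# dosage code -> printable allele pair, e.g. 0 with ref "A" alt "T" -> "AA"
allele_string <- function(code, ref, alt) {
  out <- rep(NA_character_, length(code))
  out[!is.na(code) & code == 0L] <- paste0(ref, ref)[!is.na(code) & code == 0L]
  out[!is.na(code) & code == 1L] <- paste0(ref, alt)[!is.na(code) & code == 1L]
  out[!is.na(code) & code == 2L] <- paste0(alt, alt)[!is.na(code) & code == 2L]
  out
}

phase_allele_base <- function(allele, ref, alt) {
  # allele is "ref"/"alt"/NA; returns the base, "." for NA
  out <- rep(".", length(allele))
  out[!is.na(allele) & allele == "ref"] <- ref[!is.na(allele) & allele == "ref"]
  out[!is.na(allele) & allele == "alt"] <- alt[!is.na(allele) & allele == "alt"]
  out
}

#' Write a phase table
#'
#' Writes one TSV row per site with, for each phased sample, the paternal
#' allele, maternal allele and phasing flag. Alleles are written as bases,
#' missing/unresolved as `"."`.
#'
#' @param haps List of `phased_haplotype` objects sharing the same site index.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_table <- function(haps, path) {
  stopifnot(length(haps) >= 1)
  base <- haps[[1]][, c("chrom", "pos", "site_id")]
  for (h in haps) {
    if (!identical(h$pos, haps[[1]]$pos) ||
        !identical(h$chrom, haps[[1]]$chrom)) {
      stop("phased haplotypes do not share a site index")
    }
  }
  out <- base
  for (h in haps) {
    id <- attr(h, "sample_id")
    out[[paste0(id, ".paternal_allele")]] <-
      phase_allele_base(h$pat, h$ref, h$alt)
    out[[paste0(id, ".maternal_allele")]] <-
      phase_allele_base(h$mat, h$ref, h$alt)
    out[[paste0(id, ".flag")]] <- h$flag
  }
  write_tsv(out, path)
  invisible(path)
}

#' Read a phase table written by [write_phase_table()]
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_phase_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

# Deterministic TSV writer: fixed column order as given, no quoting, no
# scientific notation, "." is left untouched (writers pre-format NA).
write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]])) {
      df2[[j]] <- format_num(df2[[j]])
    }
    df2[[j]][is.na(df2[[j]])] <- "."
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

format_num <- function(x) {
  out <- character(length(x))
  int_like <- !is.na(x) & x == round(x) & abs(x) < 2^31
  out[int_like] <- sprintf("%d", as.integer(x[int_like]))
  out[!int_like & !is.na(x)] <- sprintf("%.6f", x[!int_like & !is.na(x)])
  out[is.na(x)] <- NA_character_
  out
}

#' Write an observation/state track TSV
#'
#' One row per informative site: chrom, pos, obs, refined state and posterior
#' probability of state I.
#'
#' @param seg A `block_segmentation` (its `sites` element is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(seg, path) {
  write_tsv(seg$sites[, c("chrom", "pos", "obs", "state", "posterior_I")],
            path)
}

#' Write a blocks TSV
#'
#' BED-like table of refined haplotype blocks using 1-based closed intervals
#' (a header comment records the convention).
#'
#' @param seg A `block_segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(seg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based closed intervals", con)
  b <- seg$blocks
  b$mean_posterior <- as.numeric(b$mean_posterior)
  df2 <- b
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]])) df2[[j]] <- format_num(df2[[j]])
    df2[[j]][is.na(df2[[j]])] <- "."
  }
  utils::write.table(df2, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
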