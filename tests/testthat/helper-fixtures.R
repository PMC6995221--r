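# Shared in-code fixtures.

# Minimal genotype_matrix built directly (bypasses VCF parsing).
make_gm <- function(chrom, pos, ref, alt, gt, roles) {
  n <- length(pos)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      site_id = paste0("s", seq_len(n)),
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = names(roles), role = unname(roles),
                        stringsAsFactors = FALSE)
  embryohap:::new_genotype_matrix(sites, samples, gt)
}

roles4 <- c(F1 = "father", M1 = "mother", C1 = "reference_child",
            E1 = "embryo")

# Minimal hand-written VCF file; gts is a character matrix (rows = sites).
write_mini_vcf <- function(path, samples, chrom, pos, ref, alt, gts,
                           ids = NULL) {
  if (is.null(ids)) ids <- rep(".", length(pos))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom[i], pos[i], ids[i], ref[i], alt[i], ".",
                              "PASS", ".", "GT", gts[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# observation_track built directly from vectors.
make_track <- function(pos, obs, chrom = "chr16", embryo_id = "E1",
                       origin = "maternal") {
  structure(data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
                       obs = obs, stringsAsFactors = FALSE),
            embryo_id = embryo_id, origin = origin,
            class = c("observation_track", "data.frame"))
}

# Random track generator for oracle suites.
random_track <- function(max_len = 12, p_missing = 0.2) {
  n <- sample.int(max_len, 1)
  obs <- sample(c("i", "d", NA), n, replace = TRUE,
                prob = c((1 - p_missing) / 2, (1 - p_missing) / 2, p_missing))
  pos <- sort(sample.int(5e6, n))
  make_track(pos, obs)
}
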