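# Shared in-code fixtures: tiny on-disk files are written into tempdirs at
# test time, never stored in the repository.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_vcf <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("chr1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/0", sep = "\t")), ".vcf")
}

tiny_dosage <- function(dosages, ids = sprintf("v%d", seq_len(nrow(dosages)))) {
  # dosages: variants x samples, NA allowed
  header <- paste(c("variant_id", sprintf("S%d", seq_len(ncol(dosages)))),
                  collapse = "\t")
  rows <- vapply(seq_len(nrow(dosages)), function(i)
    paste(c(ids[i], dosages[i, ]), collapse = "\t"), "")
  write_lines_tmp(c(header, rows), ".tsv")
}

# a small two-group stratum pair for DE-chain tests
de_stratum_pair <- function(seed, frac_alt = 0, lfc = 1.5, n_features = 200) {
  list(simulate_de_counts(57, n_features, frac_alt, lfc, seed = seed),
       simulate_de_counts(6, n_features, frac_alt, lfc, seed = seed + 5000))
}

run_de_chain <- function(pair) {
  strata <- lapply(seq_along(pair), function(k)
    nb_wald_de(pair[[k]]$counts, pair[[k]]$phenotype,
               stratum = paste0("LP", k)))
  meta <- ivw_meta(strata)
  list(meta = meta, called = apply_de_thresholds(meta))
}
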