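# Small in-code text fixtures written to tempfiles at test time.

write_maf_fixture <- function(rows, path = tempfile(fileext = ".maf"),
                              comment = "#version gdc-1.0.0",
                              cols = c("Hugo_Symbol", "Variant_Classification",
                                       "Tumor_Sample_Barcode")) {
  header <- paste(cols, collapse = "\t")
  body <- vapply(rows, function(r) paste(r[cols], collapse = "\t"), character(1))
  writeLines(c(comment, header, body), path)
  path
}

maf_row <- function(gene, class, sample) {
  c(Hugo_Symbol = gene, Variant_Classification = class,
    Tumor_Sample_Barcode = sample)
}

write_gmt_fixture <- function(sets, path = tempfile(fileext = ".gmt")) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), character(1)), path)
  path
}

random_matrix <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr,
         dimnames = list(sprintf("r%02d", 1:nr), sprintf("c%02d", 1:nc)))
}
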