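# Plain-text matrix I/O shared by the panorama, pore and composite modules.
# Numbers are printed with %.17g so a write/read round trip is exact.

write_tsv_matrix <- function(m, path) {
  txt <- apply(m, 1L, function(row) {
    paste(ifelse(is.na(row), "NA", sprintf("%.17g", row)), collapse = "\t")
  })
  writeLines(txt, path)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                              na.strings = "NA", colClasses = "numeric"))
}

# write a numeric matrix (values in [0,1], row 1 = top of the image) as an
# 8-bit grayscale PNG
write_gray_png <- function(img, path) {
  png::writePNG(img, target = path)
  invisible(path)
}
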