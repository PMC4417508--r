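# tiny 24-bit uncompressed BMP writer, independent of the package's reader
write_bmp24 <- function(a, path) {
  h <- dim(a)[1]; w <- dim(a)[2]
  stride <- ((w * 3 + 3) %/% 4) * 4
  data_size <- stride * h
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  writeBin(charToRaw("BM"), con)
  w4(54 + data_size); w4(0); w4(54)
  w4(40); w4(w); w4(h)  # positive height: bottom-up
  w2(1); w2(24); w4(0); w4(data_size); w4(2835); w4(2835); w4(0); w4(0)
  for (i in h:1) {      # bottom-up row order
    row <- integer(stride)
    for (j in seq_len(w)) {
      row[(j - 1) * 3 + 1:3] <- a[i, j, c(3, 2, 1)]  # BGR
    }
    writeBin(as.raw(row), con)
  }
  invisible(path)
}

# minimal two-column xlsx (inline strings + numbers), for the spreadsheet
# parameter reader; requires the zip package
write_minimal_xlsx <- function(path, labels, values) {
  d <- tempfile("xlsx")
  dir.create(file.path(d, "_rels"), recursive = TRUE)
  dir.create(file.path(d, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(d, "xl", "worksheets"), recursive = TRUE)
  xml <- '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>'
  writeLines(c(xml,
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'), file.path(d, "[Content_Types].xml"))
  writeLines(c(xml,
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(d, "_rels", ".rels"))
  writeLines(c(xml,
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'),
    file.path(d, "xl", "workbook.xml"))
  writeLines(c(xml,
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>'), file.path(d, "xl", "_rels", "workbook.xml.rels"))
  rows <- vapply(seq_along(labels), function(i) sprintf(
    '<row r="%d"><c r="A%d" t="inlineStr"><is><t>%s</t></is></c><c r="B%d"><v>%s</v></c></row>',
    i, i, labels[i], i, format(values[i], scientific = FALSE)), "")
  writeLines(c(xml,
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"><sheetData>',
    rows, '</sheetData></worksheet>'),
    file.path(d, "xl", "worksheets", "sheet1.xml"))
  zip::zip(path, files = c("[Content_Types].xml", "_rels/.rels",
                           "xl/workbook.xml", "xl/_rels/workbook.xml.rels",
                           "xl/worksheets/sheet1.xml"), root = d)
  invisible(path)
}

# small noise-free synthetic section for fast tests
small_section <- function(seed = 1, size = 256L, n_fibers = 16L,
                          noise_sd = 0, n_objects = 12L, ...) {
  generate_section(section_spec(size = size, n_fibers = n_fibers,
                                noise_sd = noise_sd, n_objects = n_objects,
                                seed = seed, ...))
}
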