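# base64 without the line wrapping jsonlite inserts on long input
b64enc <- function(raw) gsub("\n", "", jsonlite::base64_enc(raw), fixed = TRUE)

# Minimal writers for centroided MS1 raw data.  The synthetic-data
# generator needs to emit standards-conformant files that downstream
# readers (mzR and others) accept; only the subset of mzXML 3.2 / mzML
# 1.1.0 needed for centroid MS1 scans is produced.

#' Write centroided MS1 scans to mzXML or mzML
#'
#' `scans` is a list of scan records as held by a
#' [SpectrumCollection-class]: each a list with `rt` (seconds), `mz`
#' (increasing) and `intensity`.  mzXML peaks are encoded as 32-bit
#' network-byte-order m/z-intensity pairs; mzML arrays as 64-bit
#' little-endian, both uncompressed.
#'
#' @param scans List of scan records.
#' @param path Output path.
#' @param polarity `"positive"` or `"negative"`.
#' @param ms_level MS level stamped on every scan (1 for MS1).
#' @return `path`, invisibly.
#' @export
writeMzXML <- function(scans, path, polarity = "positive", ms_level = 1L) {
  pol <- if (polarity == "positive") "+" else "-"
  body <- vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    pk <- as.vector(rbind(s$mz, s$intensity))
    b64 <- b64enc(writeBin(as.numeric(pk), raw(), size = 4L, endian = "big"))
    paste0(
      sprintf('  <scan num="%d" msLevel="%d" peaksCount="%d" retentionTime="PT%.4fS" polarity="%s" centroided="1">\n',
              i, ms_level, length(s$mz), s$rt, pol),
      sprintf('   <peaks precision="32" byteOrder="network" contentType="m/z-int" compressionType="none" compressedLen="0">%s</peaks>\n',
              b64),
      "  </scan>")
  }, "")
  xml <- c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
    sprintf(' <msRun scanCount="%d">', length(scans)),
    body,
    ' </msRun>',
    '</mzXML>')
  writeLines(xml, path)
  invisible(path)
}

#' @rdname writeMzXML
#' @export
writeMzML <- function(scans, path, polarity = "positive", ms_level = 1L) {
  enc <- function(x) b64enc(writeBin(as.numeric(x), raw(),
                                     size = 8L, endian = "little"))
  polParam <- if (polarity == "positive")
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
  specType <- if (ms_level == 1L) {
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>'
  }
  arr <- function(b64, acc, nm, unit)
    paste0('     <binaryDataArray encodedLength="', nchar(b64), '">',
           '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
           '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
           '<cvParam cvRef="MS" accession="', acc, '" name="', nm, '" value=""',
           unit, '/>',
           '<binary>', b64, '</binary></binaryDataArray>')
  body <- vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    paste0(
      sprintf('   <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
              i - 1L, i, length(s$mz)),
      '    ', specType, '\n',
      sprintf('    <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>\n', ms_level),
      '    <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '    ', polParam, '\n',
      '    <scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>\n',
      sprintf('     <scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.4f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan>\n', s$rt),
      '    </scanList>\n',
      '    <binaryDataArrayList count="2">\n',
      arr(enc(s$mz), "MS:1000514", "m/z array",
          ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"'), '\n',
      arr(enc(s$intensity), "MS:1000515", "intensity array",
          ' unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"'), '\n',
      '    </binaryDataArrayList>\n',
      '   </spectrum>')
  }, "")
  xml <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    ' <cvList count="2">',
    '  <cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '  <cv id="UO" fullName="UO" URI="http://obo.cvs.sourceforge.net/viewvc/obo/obo/ontology/phenotype/unit.obo"/>',
    ' </cvList>',
    ' <fileDescription><fileContent>',
    paste0('  ', specType),
    '  <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    ' </fileContent></fileDescription>',
    ' <softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>',
    ' <instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
    ' <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
    ' <run id="run1" defaultInstrumentConfigurationRef="ic">',
    sprintf('  <spectrumList count="%d" defaultDataProcessingRef="dp">',
            length(scans)),
    body,
    '  </spectrumList>',
    ' </run>',
    '</mzML>')
  writeLines(xml, path)
  invisible(path)
}
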