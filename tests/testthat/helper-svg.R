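# Extract all literal text nodes from an SVG file.
svg_texts <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='text']")
  xml2::xml_text(nodes)
}

# Count occurrences of each expected string among the SVG text nodes.
svg_count <- function(texts, value) sum(texts == as.character(value))
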