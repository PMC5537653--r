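#' Is a product label the "hypothetical protein" placeholder?
#'
#' Case-insensitive equality to `"hypothetical protein"` after trimming and
#' collapsing internal whitespace.
#'
#' @param product Character vector of product labels.
#' @return Logical vector.
#' @export
is_hypothetical_label <- function(product) {
  tolower(gsub("\\s+", " ", trimws(product))) == "hypothetical protein"
}

#' Read phage proteins from a FASTA file
#'
#' Header convention: `phageID|proteinID product description...`. The text
#' after the first whitespace is the product label; when absent the product
#' defaults to `"hypothetical protein"`.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param header_regex Regex with three capture groups (phage id, protein
#'   id, product) applied to each FASTA header.
#' @return A data.frame of protein records: `protein_id`, `phage_id`,
#'   `product`, `is_hypothetical`, `sequence`. Order follows the file.
#' @export
read_protein_fasta <- function(path,
                               header_regex = "^([^|]+)\\|(\\S+)\\s*(.*)$") {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    return(data.frame(protein_id = character(), phage_id = character(),
                      product = character(), is_hypothetical = logical(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  m <- regmatches(headers, regexec(header_regex, headers))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("FASTA header does not match 'phageID|proteinID product': ",
         headers[which(bad)[1]])
  phage_id <- vapply(m, `[`, "", 2L)
  protein_id <- vapply(m, `[`, "", 3L)
  product <- trimws(vapply(m, `[`, "", 4L))
  product[product == ""] <- "hypothetical protein"
  if (anyDuplicated(protein_id))
    stop("duplicate protein id: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  sequence <- as.character(set)
  if (any(!nzchar(sequence)))
    stop("empty sequence for protein: ", protein_id[!nzchar(sequence)][1])
  data.frame(protein_id = protein_id, phage_id = phage_id,
             product = product,
             is_hypothetical = is_hypothetical_label(product),
             sequence = unname(sequence), stringsAsFactors = FALSE)
}

#' Write protein records as FASTA
#'
#' Inverse of [read_protein_fasta()]: headers are
#' `phageID|proteinID product`.
#'
#' @param proteins Protein record data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- sprintf("%s|%s %s", proteins$phage_id, proteins$protein_id,
                        proteins$product)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

feature_kinds <- c("CDS", "tRNA", "prophage_region")

empty_features <- function() {
  data.frame(replicon_id = character(), start = integer(), end = integer(),
             strand = character(), kind = character(), product = character(),
             protein_id = character(), trna_isotype = character(),
             name = character(), stringsAsFactors = FALSE)
}

parse_gff_attributes <- function(text) {
  out <- list()
  if (!nzchar(text) || text == ".") return(out)
  for (field in strsplit(text, ";", fixed = TRUE)[[1]]) {
    field <- trimws(field)
    if (!nzchar(field)) next
    eq <- regexpr("=", field, fixed = TRUE)
    if (eq < 0) next
    key <- substr(field, 1, eq - 1)
    out[[key]] <- utils::URLdecode(substr(field, eq + 1, nchar(field)))
  }
  out
}

#' Read genome features from a GFF3 file
#'
#' Minimal 9-column GFF3 reader for the feature kinds this pipeline uses
#' (`CDS`, `tRNA`, `prophage_region`). Coordinates are kept 1-based
#' inclusive exactly as in the file. Lines with other feature types are
#' skipped with a warning; a malformed or inverted coordinate pair is a
#' hard error naming the line.
#'
#' @param path GFF3 file (the `##gff-version` pragma is expected; its
#'   absence is tolerated for plain 9-column TSV in the same dialect).
#' @return A data.frame of features: `replicon_id`, `start`, `end`,
#'   `strand`, `kind`, plus the `product`, `protein_id` (from `protein_id`
#'   or `ID`), `trna_isotype` and `name` (from `Name`) attributes.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  skipped <- character()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9)
      stop(sprintf("line %d: expected 9 tab-separated GFF3 columns", ln))
    start <- suppressWarnings(as.integer(fields[4]))
    end <- suppressWarnings(as.integer(fields[5]))
    if (is.na(start) || is.na(end))
      stop(sprintf("line %d: malformed coordinates '%s..%s'",
                   ln, fields[4], fields[5]))
    if (start > end)
      stop(sprintf("line %d: start %d greater than end %d", ln, start, end))
    if (start < 1)
      stop(sprintf("line %d: coordinates must be 1-based positive", ln))
    kind <- fields[3]
    if (!kind %in% feature_kinds) {
      skipped <- c(skipped, kind)
      next
    }
    attrs <- parse_gff_attributes(fields[9])
    rows[[length(rows) + 1L]] <- data.frame(
      replicon_id = fields[1], start = start, end = end,
      strand = if (fields[7] %in% c("+", "-")) fields[7] else "+",
      kind = kind,
      product = attrs$product %||% NA_character_,
      protein_id = attrs$protein_id %||% attrs$ID %||% NA_character_,
      trna_isotype = attrs$trna_isotype %||% NA_character_,
      name = attrs$Name %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0)
    warning("skipped features of unknown kind: ",
            paste(unique(skipped), collapse = ", "))
  if (length(rows) == 0) return(empty_features())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write genome features as GFF3
#'
#' @param features Feature data.frame as returned by [read_feature_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  attr_string <- function(i) {
    f <- features[i, ]
    parts <- character()
    if (!is.na(f$protein_id)) parts <- c(parts, paste0("ID=", f$protein_id),
                                         paste0("protein_id=", f$protein_id))
    if (!is.na(f$name)) parts <- c(parts, paste0("Name=", f$name))
    if (!is.na(f$product)) parts <- c(parts, paste0("product=", f$product))
    if (!is.na(f$trna_isotype)) parts <- c(parts, paste0("trna_isotype=", f$trna_isotype))
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(features)), function(i) {
               f <- features[i, ]
               paste(f$replicon_id, "viromenet", f$kind, f$start, f$end, ".",
                     f$strand, ".", attr_string(i), sep = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write a protein similarity network to disk
#'
#' `edge_list` writes a TSV `protein_a  protein_b  identity  coverage
#' evalue` with `protein_a < protein_b` lexicographically, sorted by
#' (protein_a, protein_b); `graphml` writes GraphML (via igraph) carrying
#' the `phage_id`, `product` and `degree` node attributes.
#'
#' @param net A `protein_network` from [build_network()].
#' @param path Output file.
#' @param format `"edge_list"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_list", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
    return(invisible(path))
  }
  edges <- net$edges
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  out <- data.frame(protein_a = a, protein_b = b,
                    identity = edges$identity, coverage = edges$coverage,
                    evalue = edges$evalue)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV written by [write_network()]
#'
#' @param path Edge-list file.
#' @return A data.frame with `protein_a`, `protein_b`, `identity`,
#'   `coverage`, `evalue`.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "numeric"))
}
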