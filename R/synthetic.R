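AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Generic product labels used when a synthetic protein is not hypothetical
# and no explicit family label applies.
GENERIC_PRODUCTS <- c(
  "portal protein", "major capsid protein", "terminase large subunit",
  "terminase small subunit", "integrase", "holin", "endolysin",
  "tail tape measure protein", "major tail protein", "DNA primase",
  "replication initiation protein", "tail fiber protein",
  "head maturation protease", "ATP-dependent DNA ligase",
  "adenine DNA methyltransferase")

random_protein_sequence <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

random_dna <- function(length, gc = 62) {
  p_gc <- gc / 100
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2)),
        collapse = "")
}

#' Specify a synthetic protein family
#'
#' A family is a set of homologous proteins derived from one random
#' ancestor under a star topology: each member mutates every non-motif site
#' independently with probability `p = 1 - sqrt(target_identity/100)`, so
#' the expected pairwise identity between members is approximately
#' `target_identity` (no indels).
#'
#' @param family_id Unique family label.
#' @param member_phages Character vector of phage ids, one per member;
#'   its length sets the family size.
#' @param ancestor_length Ancestor length in residues.
#' @param target_identity Expected pairwise percent identity in (0, 100].
#' @param product_label Product annotation for every member, or `NA` to let
#'   the dataset-level label policy decide.
#' @param plant_motif Optional amino-acid motif (e.g. `"NPPY"`) planted
#'   verbatim in every member and excluded from mutation.
#' @param motif_at Relative motif position in (0, 1); the motif starts at
#'   `floor(motif_at * (length - nchar(motif))) + 1`.
#' @return A `family_spec` list.
#' @export
family_spec <- function(family_id, member_phages, ancestor_length = 250L,
                        target_identity = 75, product_label = NA_character_,
                        plant_motif = NULL, motif_at = 0.5) {
  if (target_identity <= 0) stop("target_identity must be positive")
  if (target_identity > 100) stop("target_identity must not exceed 100")
  if (length(member_phages) < 1) stop("family needs at least one member")
  if (!is.null(plant_motif) && nchar(plant_motif) >= ancestor_length)
    stop("motif longer than the ancestor")
  structure(list(family_id = family_id, member_phages = member_phages,
                 n_members = length(member_phages),
                 ancestor_length = as.integer(ancestor_length),
                 target_identity = target_identity,
                 product_label = product_label,
                 plant_motif = plant_motif, motif_at = motif_at),
            class = "family_spec")
}

#' Generate one synthetic protein family
#'
#' Uses the current RNG state; seed via `set.seed()` or
#' [generate_dataset()] for reproducibility.
#'
#' @param spec A [family_spec()].
#' @return A data.frame of protein records (`protein_id` =
#'   `<family_id>_m<k>`), one per member, with the planted motif (if any)
#'   present verbatim in every sequence.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  len <- spec$ancestor_length
  ancestor <- strsplit(random_protein_sequence(len), "")[[1]]
  frozen <- integer(0)
  if (!is.null(spec$plant_motif)) {
    motif <- strsplit(spec$plant_motif, "")[[1]]
    at <- floor(spec$motif_at * (len - length(motif))) + 1L
    frozen <- seq.int(at, at + length(motif) - 1L)
    ancestor[frozen] <- motif
  }
  p <- 1 - sqrt(spec$target_identity / 100)
  members <- vapply(seq_len(spec$n_members), function(k) {
    seq <- ancestor
    mutable <- setdiff(seq_len(len), frozen)
    hit <- mutable[stats::runif(length(mutable)) < p]
    if (length(hit) > 0) {
      seq[hit] <- vapply(seq[hit], function(old)
        sample(setdiff(AA20, old), 1L), "")
    }
    paste(seq, collapse = "")
  }, "")
  data.frame(
    protein_id = sprintf("%s_m%d", spec$family_id, seq_len(spec$n_members)),
    phage_id = spec$member_phages,
    product = rep(spec$product_label, spec$n_members),
    is_hypothetical = NA,
    sequence = members, stringsAsFactors = FALSE)
}

#' Configuration for a synthetic proteome dataset
#'
#' @param seed Integer seed; identical configurations produce byte-identical
#'   outputs.
#' @param families List of [family_spec()] objects.
#' @param n_singletons Number of unrelated random background proteins.
#' @param singleton_length_range Length range (residues) for singletons.
#' @param phages Phage ids to which singletons are assigned round-robin;
#'   defaults to the union of family member phages.
#' @param hypothetical_fraction Probability that a protein without an
#'   explicit label is annotated `"hypothetical protein"`; the remainder
#'   draw a generic phage product label. Default 0.70, mirroring the
#'   typical share of hypothetical annotations in (pro)phage proteomes.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed, families = list(), n_singletons = 0L,
                         singleton_length_range = c(120L, 400L),
                         phages = NULL, hypothetical_fraction = 0.70) {
  ids <- vapply(families, `[[`, "", "family_id")
  if (anyDuplicated(ids))
    stop("duplicate family_id: ", ids[duplicated(ids)][1])
  if (is.null(phages))
    phages <- unique(unlist(lapply(families, `[[`, "member_phages")))
  if (length(phages) == 0) phages <- "P1"
  structure(list(seed = as.integer(seed), families = families,
                 n_singletons = as.integer(n_singletons),
                 singleton_length_range = as.integer(singleton_length_range),
                 phages = phages,
                 hypothetical_fraction = hypothetical_fraction),
            class = "synth_config")
}

#' Generate a synthetic proteome dataset with known family truth
#'
#' Families are generated per their specs; singletons are unrelated uniform
#' random sequences. Proteins without an explicit product label are
#' annotated `"hypothetical protein"` with probability
#' `hypothetical_fraction`, otherwise they receive a generic product label.
#'
#' @param config A [synth_config()].
#' @return A list with `proteins` (protein record data.frame) and `truth`
#'   (data.frame `protein_id`, `family_id`; `family_id` is `NA` for
#'   singletons). Every protein appears in the truth map exactly once.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fam_parts <- lapply(config$families, generate_family)
  singles <- if (config$n_singletons > 0) {
    lens <- sample(seq(config$singleton_length_range[1],
                       config$singleton_length_range[2]),
                   config$n_singletons, replace = TRUE)
    data.frame(
      protein_id = sprintf("S%03d", seq_len(config$n_singletons)),
      phage_id = rep_len(config$phages, config$n_singletons),
      product = NA_character_, is_hypothetical = NA,
      sequence = vapply(lens, random_protein_sequence, ""),
      stringsAsFactors = FALSE)
  } else NULL
  proteins <- do.call(rbind, c(fam_parts, list(singles)))
  if (is.null(proteins) || nrow(proteins) == 0)
    stop("config generates no proteins")
  # label policy for unlabeled proteins
  unlabeled <- is.na(proteins$product)
  n_u <- sum(unlabeled)
  if (n_u > 0) {
    hyp <- stats::runif(n_u) < config$hypothetical_fraction
    lab <- ifelse(hyp, "hypothetical protein",
                  sample(GENERIC_PRODUCTS, n_u, replace = TRUE))
    proteins$product[unlabeled] <- lab
  }
  proteins$is_hypothetical <- is_hypothetical_label(proteins$product)
  rownames(proteins) <- NULL
  truth <- data.frame(
    protein_id = proteins$protein_id,
    family_id = c(unlist(lapply(config$families, function(f)
      rep(f$family_id, f$n_members))),
      rep(NA_character_, config$n_singletons)),
    stringsAsFactors = FALSE)
  list(proteins = proteins, truth = truth)
}

#' Specify a prophage to plant into a synthetic host replicon
#'
#' @param prophage_length Prophage region length in bp. The default 40 kb
#'   matches typical complete temperate-phage regions in rhizobial genomes.
#' @param att_repeat_length Length of the exact direct repeat flanking the
#'   region (the attL/attR common core); 0 plants no repeat (an att-less
#'   region).
#' @param trna_isotype Isotype label of the integration-site tRNA, e.g.
#'   `"tRNA-Phe(GAA)"`.
#' @param gene_layout Ordered module labels laid out left to right across
#'   the region. Must start with `"integrase"` (the integrase gene abuts
#'   attL in tRNA-integrated prophages). Recognised labels: integrase,
#'   lysogeny, replication, MTase, terS, terL, structural, holin,
#'   endolysin, extras (hypothetical filler).
#' @return A `prophage_spec` list.
#' @export
prophage_spec <- function(prophage_length = 40000L, att_repeat_length = 17L,
                          trna_isotype = "tRNA-Phe(GAA)",
                          gene_layout = default_gene_layout()) {
  if (att_repeat_length < 0) stop("att_repeat_length must be >= 0")
  if (att_repeat_length >= prophage_length)
    stop("att_repeat_length must be smaller than prophage_length")
  if (gene_layout[1] != "integrase")
    stop("gene_layout must start with 'integrase'")
  structure(list(prophage_length = as.integer(prophage_length),
                 att_repeat_length = as.integer(att_repeat_length),
                 trna_isotype = trna_isotype, gene_layout = gene_layout),
            class = "prophage_spec")
}

#' Default prophage gene layout
#'
#' Integrase first, lysogeny control, then the replication module with the
#' DNA methyltransferase genes adjacent to the replication genes, the
#' packaging genes (terS/terL), a structural block, the lysis pair and
#' hypothetical filler.
#'
#' @param n_structural Number of structural genes.
#' @param n_extras Number of hypothetical filler genes.
#' @return Character vector of module labels.
#' @export
default_gene_layout <- function(n_structural = 12L, n_extras = 10L) {
  c("integrase", "lysogeny", "lysogeny", "MTase", "replication",
    "terS", "terL", rep("structural", n_structural),
    "holin", "endolysin", rep("extras", n_extras))
}

MODULE_PRODUCTS <- c(
  integrase = "integrase",
  lysogeny = "CI repressor protein",
  replication = "replication initiation protein",
  MTase = "adenine DNA methyltransferase",
  terS = "terminase small subunit",
  terL = "terminase large subunit",
  structural = "major capsid protein",
  holin = "holin",
  endolysin = "endolysin",
  extras = "hypothetical protein")

# longest common prefix length of the region prefix and the sequence at pos
match_len_at <- function(seq_raw, prefix_raw, pos) {
  nmax <- min(length(prefix_raw), length(seq_raw) - pos + 1L)
  if (nmax <= 0) return(0L)
  cmp <- seq_raw[pos:(pos + nmax - 1L)] != prefix_raw[seq_len(nmax)]
  mism <- which(cmp)
  if (length(mism) == 0) nmax else mism[1] - 1L
}

#' Generate a synthetic host replicon carrying one planted prophage
#'
#' Builds host background sequence at `host_gc`, inserts a prophage region
#' whose first `att_repeat_length` nt recur exactly once within `window` bp
#' downstream of the region end (the attR copy), and places a tRNA gene
#' whose 3' portion coincides with the attL repeat, emulating
#' site-specific integration that reconstitutes an intact tRNA. CDS
#' features are laid out in `gene_layout` order. Generation is validated
#' so that the planted repeat is recoverable at exactly its length; on a
#' chance collision the downstream placement is re-drawn deterministically
#' (bounded retries, then error).
#'
#' Uses the current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param spec A [prophage_spec()].
#' @param host_gc Background GC percent (default 62, a rhizobial
#'   chromosome-like value).
#' @param prophage_gc GC percent of the prophage region (default 61;
#'   prophages here run slightly AT-richer than their hosts).
#' @param flank Host background length on each side of the region, bp.
#' @param window Downstream window within which the attR copy is planted.
#' @param replicon_id Name for the replicon.
#' @param phage_name Name for the prophage region feature.
#' @return A list with `sequence` (character), `features` (feature
#'   data.frame: prophage_region, tRNA, CDS rows) and `att_truth` (one-row
#'   data.frame: `repeat_length`, `attL_start`, `attL_end`, `attR_start`,
#'   `attR_end`, `repeat_sequence`, `trna_isotype`; `repeat_length` 0 and
#'   `NA` coordinates mark an att-less region).
#' @export
generate_host_with_prophage <- function(spec, host_gc = 62, prophage_gc = 61,
                                        flank = 3000L, window = 1000L,
                                        replicon_id = "chromosome",
                                        phage_name = "phiSyn1") {
  stopifnot(inherits(spec, "prophage_spec"))
  L <- spec$att_repeat_length
  plen <- spec$prophage_length
  left <- random_dna(flank, host_gc)
  right <- random_dna(max(flank, window + L + 10L), host_gc)
  prophage <- random_dna(plen, prophage_gc)
  region_start <- flank + 1L
  region_end <- flank + plen

  att_truth <- data.frame(repeat_length = 0L, attL_start = NA_integer_,
                          attL_end = NA_integer_, attR_start = NA_integer_,
                          attR_end = NA_integer_,
                          repeat_sequence = NA_character_,
                          trna_isotype = spec$trna_isotype,
                          stringsAsFactors = FALSE)

  if (L > 0) {
    repeat_seq <- substr(prophage, 1L, L)
    prefix_raw <- charToRaw(repeat_seq)
    ok <- FALSE
    for (try in 1:10) {
      gap <- sample(50:min(400L, window - L - 2L), 1L)
      right_chars <- strsplit(right, "")[[1]]
      at <- gap + 1L  # position within the right flank
      right_chars[at:(at + L - 1L)] <- strsplit(repeat_seq, "")[[1]]
      # stop chance extension: base after attR must differ from prophage
      # base L+1 (when the repeat is shorter than the region)
      if (L < plen) {
        nxt <- substr(prophage, L + 1L, L + 1L)
        if (right_chars[at + L] == nxt)
          right_chars[at + L] <- sample(setdiff(c("A", "C", "G", "T"), nxt), 1L)
      }
      cand_right <- paste(right_chars, collapse = "")
      # validate: the prefix of length L occurs exactly once in the window,
      # at the planted spot, and no other position matches >= L
      seq_all <- paste0(left, prophage, cand_right)
      seq_raw <- charToRaw(seq_all)
      wend <- min(region_end + window, nchar(seq_all))
      lens <- vapply((region_end + 1L):wend, function(pos)
        match_len_at(seq_raw, prefix_raw, pos), 0L)
      planted_pos <- region_end + at
      if (max(lens) == L && sum(lens == L) == 1L &&
          (region_end + which.max(lens)) == planted_pos) {
        right <- cand_right
        ok <- TRUE
        break
      }
      right <- random_dna(max(flank, window + L + 10L), host_gc)
    }
    if (!ok) stop("could not plant a collision-free att repeat")
    att_truth <- data.frame(repeat_length = L,
                            attL_start = region_start,
                            attL_end = region_start + L - 1L,
                            attR_start = planted_pos,
                            attR_end = planted_pos + L - 1L,
                            repeat_sequence = repeat_seq,
                            trna_isotype = spec$trna_isotype,
                            stringsAsFactors = FALSE)
  }

  sequence <- paste0(left, prophage, right)

  # tRNA gene: 76 nt, its 3' end coinciding with the attL repeat end (or
  # abutting the region start for an att-less region).
  trna_len <- 76L
  trna_end <- if (L > 0) region_start + L - 1L else region_start - 1L
  trna_start <- max(1L, trna_end - trna_len + 1L)
  features <- data.frame(
    replicon_id = replicon_id, start = region_start, end = region_end,
    strand = "+", kind = "prophage_region", product = NA_character_,
    protein_id = NA_character_, trna_isotype = NA_character_,
    name = phage_name, stringsAsFactors = FALSE)
  features <- rbind(features, data.frame(
    replicon_id = replicon_id, start = trna_start, end = trna_end,
    strand = "+", kind = "tRNA", product = NA_character_,
    protein_id = paste0(phage_name, "_trna"),
    trna_isotype = spec$trna_isotype, name = NA_character_,
    stringsAsFactors = FALSE))

  # CDS layout across the region, in the given module order
  pos <- region_start + max(L, 60L) + 40L
  for (k in seq_along(spec$gene_layout)) {
    glen <- sample(450:1200, 1L)
    if (pos + glen - 1L > region_end - 50L)
      stop("prophage_length too small for gene_layout")
    label <- spec$gene_layout[k]
    features <- rbind(features, data.frame(
      replicon_id = replicon_id, start = pos, end = pos + glen - 1L,
      strand = "+", kind = "CDS",
      product = unname(MODULE_PRODUCTS[label]),
      protein_id = sprintf("%s_p%02d", phage_name, k),
      trna_isotype = NA_character_, name = NA_character_,
      stringsAsFactors = FALSE))
    pos <- pos + glen + sample(20:120, 1L)
  }
  rownames(features) <- NULL
  list(sequence = sequence, features = features, att_truth = att_truth)
}
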