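#' Configuration for a synthetic subtelomere reference panel
#'
#' The panel emulates the set of chromosome-end targets addressed by
#' subtelomere-specific fusion PCR primers. Members of a family (e.g. the
#' 16p/21q group of homologous chromosome ends) share their telomere-proximal
#' sequence up to a configurable per-member divergence, which is what makes
#' sister-chromatid versus same-family fusions hard to discriminate — the
#' ambiguity the caller must flag.
#'
#' Panel sequences are oriented centromere (coordinate 0) to telomere: the
#' subtelomeric unique sequence occupies `[0, subtelomere_length_bp)` and the
#' telomere repeat array sits beyond it. `telomere_origin` is therefore
#' `subtelomere_length_bp`, the 0-based coordinate of the first telomeric
#' base, from which chromatid deletions are measured.
#'
#' @param n_subtelomeres Total number of panel members; must equal the number
#'   of member names in `families`.
#' @param subtelomere_length_bp Length of each member's unique subtelomeric
#'   sequence (>= 1000).
#' @param families Named list: family name -> character vector of member
#'   names. Member names must be unique across families.
#' @param telomere_repeat Telomere repeat unit (default `TTAGGG`).
#' @param telomere_array_bp Length of terminal repeat array appended to each
#'   member.
#' @param homology_bp Length of the telomere-proximal region shared within a
#'   family before divergence is applied.
#' @param family_divergence Per-member, per-base substitution rate applied to
#'   the shared region (0.03 gives ~94% pairwise identity between members).
#' @param seed Non-negative integer seed.
#' @return A validated `sim_panel_config` list.
#' @export
sim_panel_config <- function(n_subtelomeres = 4L,
                             subtelomere_length_bp = 5000L,
                             families = list("17p" = "17p",
                                             "XpYp" = "XpYp",
                                             "16p21q" = c("16p", "21q")),
                             telomere_repeat = "TTAGGG",
                             telomere_array_bp = 300L,
                             homology_bp = 2000L,
                             family_divergence = 0.03,
                             seed = 1L) {
  members <- unlist(families, use.names = FALSE)
  if (length(members) != n_subtelomeres)
    stop("configuration error: n_subtelomeres (", n_subtelomeres,
         ") does not match the number of family members (", length(members), ")")
  if (anyDuplicated(members))
    stop("configuration error: member names must be unique")
  if (subtelomere_length_bp < 1000)
    stop("configuration error: subtelomere_length_bp must be >= 1000")
  if (!grepl("^[ACGT]+$", telomere_repeat))
    stop("configuration error: telomere_repeat must be over {A,C,G,T}")
  if (telomere_array_bp < 0 || seed < 0)
    stop("configuration error: telomere_array_bp and seed must be non-negative")
  if (family_divergence < 0 || family_divergence > 0.1)
    stop("configuration error: family_divergence outside [0, 0.1]")
  structure(list(n_subtelomeres = as.integer(n_subtelomeres),
                 subtelomere_length_bp = as.integer(subtelomere_length_bp),
                 families = families,
                 telomere_repeat = telomere_repeat,
                 telomere_array_bp = as.integer(telomere_array_bp),
                 homology_bp = as.integer(homology_bp),
                 family_divergence = family_divergence,
                 seed = as.integer(seed)),
            class = "sim_panel_config")
}

#' Build a synthetic subtelomere reference panel
#'
#' Generates one entry per configured member. Members of the same family share
#' a founder sequence over the telomere-proximal `homology_bp` bases (each
#' member then diverges at `family_divergence` per base), while the
#' centromere-proximal remainder is member-specific random sequence. The
#' result is deterministic for a fixed config and seed.
#'
#' @param config A [sim_panel_config()].
#' @return A `ReferencePanel`: list with `entries` (data.frame: name, family,
#'   length, telomere_origin, telomere_side) and `seq` (named character vector
#'   of sequences).
#' @export
build_subtelomere_panel <- function(config = sim_panel_config()) {
  if (!inherits(config, "sim_panel_config"))
    stop("configuration error: expected a sim_panel_config object")
  with_stream_seed(config$seed, "panel", {
    L <- config$subtelomere_length_bp
    hb <- min(config$homology_bp, L)
    telo <- substr(strrep(config$telomere_repeat,
                          ceiling(config$telomere_array_bp / nchar(config$telomere_repeat)) + 1L),
                   1L, config$telomere_array_bp)
    seqs <- character(0)
    fam_of <- character(0)
    for (fam in names(config$families)) {
      founder_shared <- random_dna(hb)
      for (m in config$families[[fam]]) {
        unique_part <- random_dna(L - hb)
        shared_part <- mutate_seq(founder_shared, config$family_divergence)
        seqs[[m]] <- paste0(unique_part, shared_part, telo)
        fam_of[[m]] <- fam
      }
    }
    entries <- data.frame(name = names(seqs),
                          family = unname(fam_of[names(seqs)]),
                          length = nchar(unname(seqs)),
                          telomere_origin = L,
                          telomere_side = "right",
                          stringsAsFactors = FALSE)
    structure(list(entries = entries, seq = seqs, config = config),
              class = "ReferencePanel")
  })
}

#' @export
print.ReferencePanel <- function(x, ...) {
  cat("ReferencePanel:", nrow(x$entries), "subtelomere entries,",
      length(unique(x$entries$family)), "families\n")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Write a reference panel to FASTA plus a metadata TSV
#' @param panel A `ReferencePanel`.
#' @param fasta,meta Output paths.
#' @export
write_panel <- function(panel, fasta, meta) {
  stopifnot(inherits(panel, "ReferencePanel"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(panel$seq), fasta)
  utils::write.table(panel$entries, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, meta = meta))
}

#' Read a reference panel from FASTA plus a metadata TSV
#' @param fasta,meta Input paths as written by [write_panel()].
#' @export
read_panel <- function(fasta, meta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  entries <- utils::read.delim(meta, stringsAsFactors = FALSE)
  need <- c("name", "family", "telomere_origin")
  if (!all(need %in% names(entries)))
    stop("panel metadata must contain columns: ", paste(need, collapse = ", "))
  if (!setequal(entries$name, names(seqs)))
    stop("panel FASTA names and metadata names disagree")
  if (anyDuplicated(entries$name)) stop("panel member names must be unique")
  sq <- as.character(seqs)[entries$name]
  entries$length <- nchar(unname(sq))
  if (any(entries$telomere_origin < 0 | entries$telomere_origin > entries$length))
    stop("telomere_origin outside sequence bounds")
  if (is.null(entries$telomere_side))
    entries$telomere_side <- ifelse(entries$telomere_origin <= entries$length / 2, "left", "right")
  structure(list(entries = entries, seq = sq, config = NULL), class = "ReferencePanel")
}
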