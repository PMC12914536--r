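# Cross-species gene-symbol harmonization: case conventions + curated aliases.

.aliasEnv <- new.env(parent = emptyenv())

.aliasTable <- function() {
  if (is.null(.aliasEnv$tab)) {
    path <- system.file("extdata", "gene_aliases.tsv",
                        package = "coactivate", mustWork = TRUE)
    .aliasEnv$tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .aliasEnv$tab
}

.titleCase <- function(x) {
  paste0(toupper(substring(x, 1L, 1L)), tolower(substring(x, 2L)))
}

#' Harmonize gene symbols across species conventions
#'
#' Applies (i) a curated alias table mapping retired or synonymous symbols
#' to their canonical form (at minimum Tmem173 -> Sting1, Mb21d1 -> Cgas,
#' Figf -> Vegfd, Pigf -> Pgf) and (ii) the case convention of the target
#' species: Title-case for mouse, upper-case for human, pig and macaque.
#' Symbols without an alias entry pass through unchanged apart from case;
#' the mapping is deterministic and idempotent. Symbols that changed are
#' recorded in the `"mapping"` attribute of the result.
#'
#' @param symbols Character vector of gene symbols.
#' @param from,to Source and target species
#'   (`"mouse"`, `"human"`, `"pig"`, `"macaque"`).
#' @return Character vector of canonical symbols in the target convention,
#'   with a `"mapping"` attribute (data.frame `input`/`output` of changed
#'   symbols, possibly empty).
#' @examples
#' harmonizeGenes(c("Kdr", "Tmem173"), "mouse", "human")  # KDR, STING1
#' harmonizeGenes("Tmem173", "mouse", "mouse")            # Sting1
#' @export
harmonizeGenes <- function(symbols, from = "mouse", to = from) {
  for (sp in c(from, to)) if (!sp %in% .SPECIES)
    stop(sprintf("unknown species tag '%s'; must be one of %s", sp,
                 paste(.SPECIES, collapse = ", ")))
  symbols <- as.character(symbols)
  up <- toupper(symbols)
  tab <- .aliasTable()
  hit <- match(up, tab$alias)
  up[!is.na(hit)] <- tab$canonical[hit[!is.na(hit)]]
  out <- if (to == "mouse") .titleCase(up) else up
  changed <- which(out != symbols)
  attr(out, "mapping") <- data.frame(input = symbols[changed],
                                     output = out[changed],
                                     stringsAsFactors = FALSE)
  out
}

#' Harmonize a signature to a target species
#'
#' Convenience wrapper applying [harmonizeGenes()] to a [GeneSignature],
#' resolving any duplicates the alias collapse may create (first
#' occurrence kept, in signature order).
#'
#' @param sig A [GeneSignature].
#' @param to Target species.
#' @return A [GeneSignature] in the target convention.
#' @export
harmonizeSignature <- function(sig, to) {
  genes <- harmonizeGenes(sigGenes(sig), sigSpecies(sig), to)
  genes <- genes[!duplicated(genes)]
  GeneSignature(sigName(sig), genes, species = to, source = sig@source)
}
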