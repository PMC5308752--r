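## Packaged resources: the 24-gene amplicon panel catalogue, protein-domain
## coordinate tables, the synthetic coding-sequence model behind annotation
## and simulation, and the default site blacklist.

.oamlmut_cache <- new.env(parent = emptyenv())

#' Genes of the targeted OAML amplicon panel
#'
#' Returns the catalogue of the 24 genes covered by the amplicon panel:
#' HUGO symbol, common alias, signalling-pathway assignment, protein length
#' (amino acids) and the genomic anchor of the gene's coding model used by
#' the synthetic reference (see [synthetic_cds()]).
#'
#' @return A data.frame with columns `gene`, `alias`, `pathway`,
#'   `protein_length`, `chrom`, `cds_anchor`.
#' @export
#' @examples
#' head(panel_genes())
panel_genes <- function() {
  if (is.null(.oamlmut_cache$panel_genes)) {
    path <- system.file("extdata", "panel_genes.tsv", package = "oamlmut",
                        mustWork = TRUE)
    .oamlmut_cache$panel_genes <- utils::read.table(
      path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  .oamlmut_cache$panel_genes
}

#' Pathway gene sets of the panel
#'
#' The NF-kB set contains every panel gene whose pathway assignment mentions
#' NF-kB (19 genes, canonical and non-canonical members); the epigenetic,
#' Notch and apoptosis sets hold the remainder.
#'
#' @param name One of `"NF-kB"`, `"Notch"`, `"Extrinsic apoptosis"`,
#'   `"Methylation"`.
#' @return Character vector of member gene symbols.
#' @export
gene_set <- function(name = c("NF-kB", "Notch", "Extrinsic apoptosis",
                              "Methylation")) {
  name <- match.arg(name)
  pg <- panel_genes()
  if (name == "NF-kB") {
    pg$gene[grepl("NF-kB", pg$pathway, fixed = TRUE)]
  } else {
    pg$gene[pg$pathway == name]
  }
}

#' Protein domain coordinate map
#'
#' Domain intervals (1-based amino-acid coordinates, non-overlapping within
#' a gene) for the proteins whose mutation distribution the pipeline
#' summarises in lollipop form: NOTCH1, NOTCH2, KMT2D and TNFAIP3. Values
#' follow standard protein annotations (UniProt-style feature tables) and
#' ship as an editable TSV resource.
#'
#' @param path Optional path to an alternative domain table with columns
#'   `gene`, `domain`, `aa_start`, `aa_end`.
#' @return data.frame with those four columns.
#' @export
read_domain_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "protein_domains.tsv", package = "oamlmut",
                        mustWork = TRUE)
  }
  dm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "domain", "aa_start", "aa_end")
  if (!all(need %in% names(dm)))
    stop("domain map must have columns: ", paste(need, collapse = ", "))
  bad <- dm$aa_start > dm$aa_end
  if (any(bad)) stop("domain with aa_start > aa_end: ", dm$domain[bad][1])
  ## enforce the partition property within each gene
  for (g in unique(dm$gene)) {
    d <- dm[dm$gene == g, , drop = FALSE]
    d <- d[order(d$aa_start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$aa_start[-1] <= d$aa_end[-nrow(d)]))
      stop("overlapping domains for gene ", g)
  }
  dm
}

## --- genetic code -----------------------------------------------------------

.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L",
  CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V",
  GTA = "V", GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
  TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C",
  TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G",
  GGG = "G")

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", "*" = "Ter")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

translate_codon <- function(codon) {
  aa <- .GENETIC_CODE[toupper(codon)]
  ifelse(is.na(aa), "X", aa)
}

## --- synthetic coding model -------------------------------------------------

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random stream (the synthetic reference must be identical regardless of
## user-level seeding).
with_fixed_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic coding sequence of a panel gene
#'
#' The package carries no genome; annotation and simulation run against a
#' deterministic synthetic coding model: one contiguous plus-strand CDS per
#' panel gene, of length `3 * protein_length`, anchored at the genomic
#' coordinate in [panel_genes()]. The sequence for each gene is generated
#' once from a fixed gene-specific seed (bit-identical across sessions and
#' platforms), internal stop codons are rewritten, and the MYD88 model
#' carries the real Leu265 codon (CTG at CDS 793-795) so that the canonical
#' chr3:38182641 T>C hotspot annotates as Leu265Pro, its published GRCh37
#' coordinate. All other sequence content is synthetic.
#'
#' @param gene HUGO symbol of a panel gene.
#' @return Single character string, the CDS (5' to 3', coding strand).
#' @export
synthetic_cds <- function(gene) {
  key <- paste0("cds_", gene)
  cached <- .oamlmut_cache[[key]]
  if (!is.null(cached)) return(cached)
  pg <- panel_genes()
  i <- match(gene, pg$gene)
  if (is.na(i)) stop("not a panel gene: ", gene)
  len <- pg$protein_length[i] * 3L
  seed <- sum(utf8ToInt(gene) * seq_along(utf8ToInt(gene))) + 20160823L
  bases <- with_fixed_seed(seed, sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE))
  ## no internal stops: rewrite any stop codon by forcing its first base to C
  starts <- seq(1L, len - 2L, by = 3L)
  codons <- paste0(bases[starts], bases[starts + 1L], bases[starts + 2L])
  stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(stop_idx)) bases[starts[stop_idx]] <- "C"
  if (gene == "MYD88") bases[793:795] <- c("C", "T", "G")
  seq <- paste(bases, collapse = "")
  .oamlmut_cache[[key]] <- seq
  seq
}

#' Coding context of a genomic position
#'
#' Maps a genomic position to its 1-based CDS coordinate, codon number,
#' frame and reference codon under the synthetic coding model. Returns
#' `NULL` when the position does not fall inside the gene's coding model.
#'
#' @param gene Panel gene symbol.
#' @param pos 1-based genomic position (GRCh37 convention).
#' @return List with `cds_pos`, `codon_number`, `frame` (0-2), `ref_codon`,
#'   `strand`, or `NULL`.
#' @export
cds_context <- function(gene, pos) {
  pg <- panel_genes()
  i <- match(gene, pg$gene)
  if (is.na(i)) return(NULL)
  cds_pos <- pos - pg$cds_anchor[i] + 1L
  len <- pg$protein_length[i] * 3L
  if (is.na(cds_pos) || cds_pos < 1L || cds_pos > len) return(NULL)
  codon_number <- (cds_pos - 1L) %/% 3L + 1L
  frame <- (cds_pos - 1L) %% 3L
  seq <- synthetic_cds(gene)
  ref_codon <- substr(seq, (codon_number - 1L) * 3L + 1L, codon_number * 3L)
  list(cds_pos = cds_pos, codon_number = codon_number, frame = frame,
       ref_codon = ref_codon, strand = "+")
}

## reference base(s) at a genomic position under the synthetic coding model
synthetic_ref <- function(gene, pos, width = 1L) {
  ctx <- cds_context(gene, pos)
  if (is.null(ctx)) return(NA_character_)
  substr(synthetic_cds(gene), ctx$cds_pos, ctx$cds_pos + width - 1L)
}

#' Default site blacklist
#'
#' Recurrent artifact sites removed from every analysis. The shipped table
#' holds the recurrent NOTCH1 1-bp deletion that failed orthogonal
#' validation (removing base chr9:139390945, GRCh37; recorded left-anchored
#' at 139390944 with the package's synthetic reference alleles).
#'
#' @param path Optional path to an alternative blacklist TSV with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @return data.frame keyed by (chrom, pos, ref, alt).
#' @export
default_blacklist <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "blacklist_default.tsv",
                        package = "oamlmut", mustWork = TRUE)
  }
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "character",
                                   "character"))
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
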