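GENIC_LEVELS <- c("IG", "DP", "PP", "GB", "DS")
CGI_LEVELS <- c("CGI", "SHO", "SHE", "NC")

#' Assign genic categories relative to the nearest TSS
#'
#' The genome is divided into five mutually exclusive windows around each
#' probe's nearest transcription start site: intergenic (IG, > 10 kb from
#' the nearest TSS), distal promoter (DP, -10 kb to -1.5 kb), proximal
#' promoter (PP, -1.5 kb to +500 bp), gene body (GB, +500 bp to the 3' end
#' of the same gene) and downstream (DS, 3' end to +5 kb beyond it).
#' Distances are strand-aware (upstream negative). The nearest TSS is the
#' one at minimum absolute genomic distance; ties are broken by the
#' lexicographically smallest gene id. Boundary convention: DP is
#' \[-10000, -1500), PP is \[-1500, +500\], GB is (+500, gene length\],
#' DS is (length, length + 5000\].
#'
#' @param pos Integer vector of probe positions (1-based).
#' @param chrom Character vector of probe chromosomes (same length).
#' @param genes Gene model data.frame (`gene_id`, `chrom`, `strand`, `tss`,
#'   `end3`).
#' @return data.frame with `category`, `gene_id`, `distance` (signed bp to
#'   the nearest TSS; NA when the chromosome has no gene, category IG).
#' @export
assign_genic_region <- function(pos, chrom, genes) {
  n <- length(pos)
  if (length(chrom) != n) stop_("pos and chrom lengths differ")
  genes <- validate_gene_models(genes)
  out <- data.frame(category = rep("IG", n), gene_id = NA_character_,
                    distance = NA_integer_, stringsAsFactors = FALSE)
  no_gene_chroms <- character()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) { no_gene_chroms <- c(no_gene_chroms, ch); next }
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    tt <- g$tss
    for (i in idx) {
      p <- pos[i]
      ad <- abs(tt - p)
      dmin <- min(ad)
      hit <- which(ad == dmin)
      j <- hit[order(g$gene_id[hit])][1L]
      sgn <- if (g$strand[j] == "+") 1L else -1L
      d <- sgn * (p - g$tss[j])
      len <- abs(g$end3[j] - g$tss[j])
      cat <- if (d >= -10000 && d < -1500) "DP"
        else if (d >= -1500 && d <= 500) "PP"
        else if (d > 500 && d <= len) "GB"
        else if (d > len && d <= len + 5000) "DS"
        else "IG"
      out$category[i] <- cat
      out$gene_id[i] <- g$gene_id[j]
      out$distance[i] <- d
    }
  }
  if (length(no_gene_chroms))
    message("assign_genic_region: no gene model on ",
            collapse_ids(no_gene_chroms), "; probes there set to IG")
  out
}

#' Assign CGI-centric categories
#'
#' A probe is CGI if it falls inside a (merged) CpG island, SHO (shore) if
#' its distance to the nearest island edge is at most `shore_width`, SHE
#' (shelf) if the distance is at most `shore_width + shelf_width`, and NC
#' (non-CGI) otherwise. Overlapping islands are merged before edge
#' distances are computed. Distance is measured in bases from the probe to
#' the closest island boundary (a probe one base past the island edge is
#' at distance 1).
#'
#' @param pos,chrom Probe positions (1-based) and chromosomes.
#' @param cgis Interval data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open, as returned by [read_intervals()]). May be empty.
#' @param shore_width,shelf_width Widths in bp (defaults 2000 each).
#' @return Character vector of categories (CGI/SHO/SHE/NC).
#' @export
assign_cgi_region <- function(pos, chrom, cgis,
                              shore_width = 2000L, shelf_width = 2000L) {
  n <- length(pos)
  out <- rep("NC", n)
  if (is.null(cgis) || !nrow(cgis)) return(out)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ci <- cgis[cgis$chrom == ch, , drop = FALSE]
    if (!nrow(ci)) next
    # convert 0-based half-open to 1-based closed, then merge overlaps
    ir <- IRanges::reduce(IRanges::IRanges(ci$start + 1L, ci$end))
    pr <- IRanges::IRanges(pos[idx], pos[idx])
    hit <- IRanges::distanceToNearest(pr, ir)
    gap <- rep(NA_integer_, length(idx))
    gap[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    dist_edge <- ifelse(gap == 0L, 0L, gap + 1L)
    out[idx] <- ifelse(is.na(dist_edge), "NC",
                ifelse(dist_edge == 0L, "CGI",
                ifelse(dist_edge <= shore_width, "SHO",
                ifelse(dist_edge <= shore_width + shelf_width, "SHE", "NC"))))
  }
  out
}

#' Annotate a probe manifest
#'
#' Adds the genic category, nearest gene, signed TSS distance and
#' CGI-centric category to every probe of a minimal manifest.
#'
#' @param manifest data.frame with `probe_id`, `chrom`, `pos`.
#' @param genes Gene models.
#' @param cgis CGI intervals (0-based half-open), or NULL for none.
#' @param shore_width,shelf_width Passed to [assign_cgi_region()].
#' @return The manifest with columns `genic`, `nearest_gene`,
#'   `tss_distance`, `cgi` appended.
#' @export
annotate_manifest <- function(manifest, genes, cgis = NULL,
                              shore_width = 2000L, shelf_width = 2000L) {
  gen <- assign_genic_region(manifest$pos, manifest$chrom, genes)
  manifest$genic <- gen$category
  manifest$nearest_gene <- gen$gene_id
  manifest$tss_distance <- gen$distance
  manifest$cgi <- assign_cgi_region(manifest$pos, manifest$chrom, cgis,
                                    shore_width, shelf_width)
  manifest
}

#' Proximal-promoter and gene-body probe sets of a gene
#'
#' Returns exactly the probes whose nearest-TSS gene is `gene_id` and whose
#' genic category is PP (proximal promoter) or GB (gene body). Because
#' every probe has a single nearest gene, the sets across genes are
#' disjoint by construction.
#'
#' @param gene_id Single gene id.
#' @param manifest Annotated manifest (see [annotate_manifest()]).
#' @param genes Optional gene model table; when given, `gene_id` must be
#'   one of its genes (a known gene with no nearby probes yields two empty
#'   sets rather than an error).
#' @return List with character vectors `pp` and `gb`.
#' @export
gene_region_probes <- function(gene_id, manifest, genes = NULL) {
  if (is.null(manifest$genic) || is.null(manifest$nearest_gene))
    stop_("manifest is not annotated; run annotate_manifest() first")
  if (length(gene_id) != 1L) stop_("gene_id must be a single id")
  sel <- !is.na(manifest$nearest_gene) & manifest$nearest_gene == gene_id
  known <- if (is.null(genes)) unique(manifest$nearest_gene) else genes$gene_id
  if (!gene_id %in% known)
    stop_("unknown gene '%s'", gene_id)
  list(pp = manifest$probe_id[sel & manifest$genic == "PP"],
       gb = manifest$probe_id[sel & manifest$genic == "GB"])
}
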