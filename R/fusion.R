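## Fusion-transcript and breakpoint classification relative to retrocopies.
##
## A gene "hosts" a retrocopy when the retrocopy span lies fully inside the
## gene's transcribed span; partial overlap is logged as marginal and
## excluded from category assignment. Categories: parental_x_host (one
## partner is the parental gene of a retrocopy hosted by the other),
## retro_x_parental (one partner is a retrocopy, the other its parent),
## host_x_host (both partners host retrocopies of one common parental
## gene), else other.

## host map: data.frame retro_id, gene_id for full containment
host_map <- function(catalog, ann) {
  genes <- gene_spans(ann)
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    inside <- genes$chrom == catalog$chrom[i] &
      genes$start <= catalog$start[i] & genes$end >= catalog$end[i]
    if (any(inside))
      rows[[length(rows) + 1L]] <- data.frame(
        retro_id = catalog$retro_id[i], gene_id = genes$gene_id[inside],
        stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(retro_id = character(), gene_id = character())
}

#' Classify a fusion's relationship to the retrocopy catalog
#'
#' @param fusions a [fusion_table()].
#' @param catalog retrocopy catalog.
#' @param ann annotation (for host-gene containment).
#' @return data.frame fusion_id, category, retro_ids (comma-separated
#'   implicated retrocopies; empty for `other`).
#' @export
classify_fusion_category <- function(fusions, catalog, ann) {
  hosts <- host_map(catalog, ann)
  parent_of <- stats::setNames(catalog$parental_gene_id, catalog$retro_id)
  out <- data.frame(fusion_id = fusions$fusion_id, category = "other",
                    retro_ids = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(fusions))) {
    g5 <- fusions$gene5_id[i]; g3 <- fusions$gene3_id[i]
    assign_cat <- function(cat, rids) {
      out$category[i] <<- cat
      out$retro_ids[i] <<- paste(unique(rids), collapse = ",")
    }
    # retro_x_parental: one partner is a retrocopy id, the other its parent
    for (pp in list(c(g5, g3), c(g3, g5))) {
      if (pp[1] %in% catalog$retro_id && parent_of[[pp[1]]] == pp[2]) {
        assign_cat("retro_x_parental", pp[1]); break
      }
    }
    if (out$category[i] != "other") next
    # parental_x_host: partner A parents a retrocopy hosted by partner B
    for (pp in list(c(g5, g3), c(g3, g5))) {
      rids <- catalog$retro_id[catalog$parental_gene_id == pp[1]]
      hosted <- rids[rids %in% hosts$retro_id[hosts$gene_id == pp[2]]]
      if (length(hosted)) { assign_cat("parental_x_host", hosted); break }
    }
    if (out$category[i] != "other") next
    # host_x_host: both partners host retrocopies of one common parent
    r5 <- hosts$retro_id[hosts$gene_id == g5]
    r3 <- hosts$retro_id[hosts$gene_id == g3]
    if (length(r5) && length(r3)) {
      common <- intersect(parent_of[r5], parent_of[r3])
      if (length(common)) {
        rids <- c(r5[parent_of[r5] %in% common], r3[parent_of[r3] %in% common])
        assign_cat("host_x_host", rids)
      }
    }
  }
  out
}

#' Classify one breakpoint relative to one retrocopy
#'
#' `in_body` when the position falls inside the half-open retrocopy span
#' (the start base counts, the end base does not); `downstream_near` when
#' outside but within `near_max` bases downstream of the retrocopy 3' end
#' (strand-aware); `distant` otherwise on the same chromosome (upstream or
#' far positions; distance to the nearest span edge reported); `unrelated`
#' on a different chromosome.
#'
#' @param chrom,pos breakpoint location (0-based position).
#' @param retro one catalog row (retro_id, chrom, start, end, strand).
#' @param near_max downstream_near bound in bases (default 1000).
#' @return list with `class` and `distance` (NA for in_body/unrelated).
#' @export
classify_breakpoint <- function(chrom, pos, retro, near_max = 1000) {
  if (chrom != retro$chrom) return(list(class = "unrelated", distance = NA_real_))
  if (pos >= retro$start && pos < retro$end)
    return(list(class = "in_body", distance = NA_real_))
  # distance 1 = first base past the span on the downstream side
  downstream_d <- if (retro$strand == "+") pos - (retro$end - 1L) else retro$start - pos
  if (downstream_d > 0 && downstream_d <= near_max)
    return(list(class = "downstream_near", distance = downstream_d))
  dist <- min(abs(pos - retro$start), abs(pos - (retro$end - 1L)))
  list(class = "distant", distance = dist)
}

#' Classify all breakpoints of a fusion table against implicated retrocopies
#'
#' Combines [classify_fusion_category()] with per-breakpoint classes for
#' every implicated retrocopy; fusions in category `other` are compared
#' against no retrocopy.
#'
#' @param fusions a [fusion_table()].
#' @param catalog retrocopy catalog.
#' @param ann annotation.
#' @param near_max downstream_near bound.
#' @return data.frame fusion_id, category, retro_id, breakpoint
#'   (`5p`/`3p`), class, distance.
#' @export
classify_fusions <- function(fusions, catalog, ann, near_max = 1000) {
  cats <- classify_fusion_category(fusions, catalog, ann)
  rows <- list()
  for (i in seq_len(nrow(cats))) {
    if (cats$category[i] == "other" || !nzchar(cats$retro_ids[i])) next
    rids <- strsplit(cats$retro_ids[i], ",", fixed = TRUE)[[1]]
    for (rid in rids) {
      retro <- catalog[catalog$retro_id == rid, ]
      for (bp in c("5p", "3p")) {
        chrom <- if (bp == "5p") fusions$chrom5[i] else fusions$chrom3[i]
        pos <- if (bp == "5p") fusions$pos5[i] else fusions$pos3[i]
        cl <- classify_breakpoint(chrom, pos, retro, near_max)
        rows[[length(rows) + 1L]] <- data.frame(
          fusion_id = cats$fusion_id[i], category = cats$category[i],
          retro_id = rid, breakpoint = bp, class = cl$class,
          distance = cl$distance, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fusion_id = character(), category = character(),
               retro_id = character(), breakpoint = character(),
               class = character(), distance = numeric())
  rownames(out) <- NULL
  out
}
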