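#' Exclusive intersections of named gene sets
#'
#' Partitions the union of two or more gene sets into the regions of an UpSet
#' analysis: a gene belongs to exactly one region, the subset of sets that
#' all contain it. Duplicate IDs within a set are dropped silently (with a
#' message), matching the behavior expected of bare ID-list inputs.
#'
#' @param sets Either a named list of character vectors, or a data frame with
#'   columns `set` and `gene`.
#' @return A `set_relation`: list with `set_names`, `membership` (tibble:
#'   `gene_id` plus one logical column per set), and `regions` (tibble:
#'   `region` label like `"A&B"`, `degree`, `size`, `genes` list-column),
#'   ordered by size descending with ties broken by region label.
#' @export
exclusive_intersections <- function(sets) {
  if (is.data.frame(sets)) {
    if (!all(c("set", "gene") %in% names(sets))) {
      coex_abort("Data-frame input needs columns `set` and `gene`.")
    }
    sets <- split(sets$gene, sets$set)
  }
  if (!is.list(sets) || length(sets) < 2L) {
    coex_abort("At least two gene sets are required.", class = "coexnet_value_error")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets))) || anyDuplicated(names(sets))) {
    coex_abort("Sets must have unique non-empty names.")
  }
  set_names <- names(sets)
  sets <- purrr::imap(sets, function(s, nm) {
    s <- as.character(s)
    if (anyDuplicated(s)) {
      inform(sprintf("Set '%s': dropped %d duplicate ID(s).", nm, sum(duplicated(s))))
    }
    unique(s)
  })
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- tibble(gene_id = universe)
  for (nm in set_names) membership[[nm]] <- universe %in% sets[[nm]]
  pattern <- apply(as.matrix(membership[set_names]), 1L, function(row) {
    paste(set_names[row], collapse = "&")
  })
  regions <- tibble(gene_id = universe, region = pattern) %>%
    group_by(.data$region) %>%
    summarise(degree = length(strsplit(.data$region[1L], "&", fixed = TRUE)[[1L]]),
              size = dplyr::n(), genes = list(.data$gene_id), .groups = "drop") %>%
    arrange(desc(.data$size), .data$region)
  structure(list(set_names = set_names, membership = membership,
                 regions = regions), class = "set_relation")
}

#' @export
print.set_relation <- function(x, ...) {
  cat(sprintf("<set_relation> %d sets, %d genes in union, %d non-empty regions\n",
              length(x$set_names), nrow(x$membership), nrow(x$regions)))
  print(x$regions[c("region", "degree", "size")])
  invisible(x)
}

#' UpSet summary table
#'
#' @param sr `set_relation` from [exclusive_intersections()].
#' @return A tibble of (`region`, `degree`, `size`) rows in the relation's
#'   order, with a `set_totals` attribute giving each input set's total size
#'   (regions containing the set summed; empty input sets report 0).
#' @export
upset_table <- function(sr) {
  out <- sr$regions[c("region", "degree", "size")]
  totals <- tibble(
    set = sr$set_names,
    total = vapply(sr$set_names, function(nm) sum(sr$membership[[nm]]),
                   integer(1), USE.NAMES = FALSE)
  )
  attr(out, "set_totals") <- totals
  out
}

#' Genes in one exclusive region
#'
#' Convenience accessor for handing a region's gene list to [enrich()].
#'
#' @param sr `set_relation`.
#' @param region Region label, e.g. `"A&B"`.
#' @return Character vector of gene IDs.
#' @export
region_genes <- function(sr, region) {
  idx <- match(region, sr$regions$region)
  if (is.na(idx)) {
    coex_abort(sprintf("No region '%s'; available: %s.", region,
                       toString(sr$regions$region)))
  }
  sr$regions$genes[[idx]]
}

#' Read plain-text gene ID lists as named sets
#'
#' One ID per line; set names default to the file base names.
#'
#' @param paths Character vector of >= 2 file paths.
#' @param names Optional set names.
#' @return Named list of character vectors, ready for
#'   [exclusive_intersections()].
#' @export
read_gene_sets <- function(paths, names = NULL) {
  sets <- lapply(paths, function(p) {
    ids <- readr::read_lines(p, progress = FALSE)
    ids[nzchar(stringr::str_trim(ids))]
  })
  names(sets) <- names %||% sub("\\.[^.]*$", "", basename(paths))
  sets
}
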