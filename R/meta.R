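#' Build a raw multi-study gene-list collection
#'
#' A collection of per-study differential gene lists as extracted from
#' publications: each record is a raw identifier in some namespace together
#' with the reported direction of change relative to FTC (`"up"` = higher in
#' carcinoma).
#'
#' @param records data frame with columns `study_id`, `raw_id`, `namespace`,
#'   `direction` (`"up"`/`"down"`).
#' @return The validated data frame, class `raw_study_collection`.
#' @export
raw_study_collection <- function(records) {
  need <- c("study_id", "raw_id", "namespace", "direction")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (!all(records$direction %in% c("up", "down")))
    stop("'direction' must be 'up' or 'down'")
  records <- as.data.frame(records)[need]
  class(records) <- c("raw_study_collection", "data.frame")
  records
}

#' Read an identifier-mapping table
#'
#' A static snapshot mapping `(raw_id, namespace)` pairs onto canonical
#' Entrez-style gene ids and symbols; used instead of live lookups so that
#' meta-analyses are reproducible. Within a namespace a raw id must map to a
#' single canonical id.
#'
#' @param mapping data frame with columns `raw_id`, `namespace`, `gene_id`,
#'   `symbol`.
#' @return The validated data frame, class `id_map`.
#' @export
id_map <- function(mapping) {
  need <- c("raw_id", "namespace", "gene_id", "symbol")
  if (!all(need %in% names(mapping)))
    stop("mapping must have columns: ", paste(need, collapse = ", "))
  key <- paste(mapping$namespace, mapping$raw_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  conflict <- vapply(dup, function(k)
    length(unique(mapping$gene_id[key == k])) > 1, logical(1))
  if (any(conflict))
    stop("raw ids mapping to multiple canonical ids within one namespace: ",
         paste(sub("\r", "/", dup[conflict]), collapse = ", "))
  mapping <- as.data.frame(mapping)[need]
  class(mapping) <- c("id_map", "data.frame")
  mapping
}

#' Harmonize raw study gene lists to canonical identifiers
#'
#' Maps every record of a raw collection to its canonical gene id. Records in
#' the built-in `"entrez"` namespace pass through unchanged; all other
#' namespaces must be covered by the supplied [id_map()], otherwise an error
#' is raised. Unmapped raw ids are dropped and counted. Within each study,
#' duplicate reports of the same canonical gene collapse to one record; if a
#' study reports the same gene in both directions the record is unusable and
#' dropped (and counted).
#'
#' @param collection a [raw_study_collection()] or an already-canonical
#'   `study_collection` (returned unchanged).
#' @param idmap an [id_map()]; may be omitted when all records are already in
#'   the `"entrez"` namespace.
#' @return A canonical `study_collection` data frame (`study_id`, `gene_id`,
#'   `symbol`, `direction`) with attributes `n_unmapped` and
#'   `n_direction_conflicts`.
#' @export
harmonize_ids <- function(collection, idmap = NULL) {
  if (inherits(collection, "study_collection")) return(collection)
  stopifnot(inherits(collection, "raw_study_collection"))
  ns <- unique(collection$namespace)
  known <- c("entrez", if (!is.null(idmap)) unique(idmap$namespace))
  if (length(setdiff(ns, known)))
    stop("unknown namespace(s) not covered by the id map: ",
         paste(setdiff(ns, known), collapse = ", "))
  gene_id <- rep(NA_integer_, nrow(collection))
  symbol <- rep(NA_character_, nrow(collection))
  is_entrez <- collection$namespace == "entrez"
  gene_id[is_entrez] <- as.integer(collection$raw_id[is_entrez])
  symbol[is_entrez] <- as.character(collection$raw_id[is_entrez])
  if (!is.null(idmap)) {
    key <- paste(collection$namespace, collection$raw_id, sep = "\r")
    mkey <- paste(idmap$namespace, idmap$raw_id, sep = "\r")
    hit <- match(key, mkey)
    use <- !is_entrez & !is.na(hit)
    gene_id[use] <- idmap$gene_id[hit[use]]
    symbol[use] <- idmap$symbol[hit[use]]
    if (!is.null(idmap) && any(is_entrez)) {
      # prefer the map's symbol when it knows the entrez id
      ehit <- match(paste("entrez", collection$raw_id, sep = "\r"), mkey)
      symbol[is_entrez & !is.na(ehit)] <-
        idmap$symbol[ehit[is_entrez & !is.na(ehit)]]
    }
  }
  unmapped <- is.na(gene_id)
  n_unmapped <- sum(unmapped)
  if (n_unmapped)
    message(n_unmapped, " record(s) dropped: raw id absent from the id map")
  out <- data.frame(study_id = collection$study_id[!unmapped],
                    gene_id = gene_id[!unmapped],
                    symbol = symbol[!unmapped],
                    direction = collection$direction[!unmapped],
                    stringsAsFactors = FALSE)
  # within-study collapse; direction conflicts are unusable
  key <- paste(out$study_id, out$gene_id, sep = "\r")
  ndir <- tapply(out$direction, key, function(d) length(unique(d)))
  conflict_keys <- names(ndir)[ndir > 1]
  n_conflicts <- length(conflict_keys)
  if (n_conflicts)
    message(n_conflicts, " within-study direction conflict(s) dropped")
  out <- out[!key %in% conflict_keys, , drop = FALSE]
  out <- out[!duplicated(paste(out$study_id, out$gene_id, sep = "\r")), ,
             drop = FALSE]
  out <- out[order(out$study_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("study_collection", "data.frame")
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_direction_conflicts") <- n_conflicts
  out
}

#' Tally cross-study votes per gene
#'
#' Counts, for every canonical gene, the number of studies reporting it, the
#' per-study directions, whether the directions are concordant, and the
#' consensus direction (only defined when concordant). Rows are ordered by
#' count (descending) then canonical gene id (ascending), so the table is
#' deterministic and permutation-invariant in the input studies.
#'
#' @param collection a canonical `study_collection` (see [harmonize_ids()]).
#' @return A data frame of class `vote_table` with columns `gene_id`,
#'   `symbol`, `count`, `directions` (collapsed string), `concordant`,
#'   `consensus_direction` (`NA` when discordant) and `studies`.
#' @export
tally_votes <- function(collection) {
  stopifnot(inherits(collection, "study_collection"))
  if (nrow(collection) == 0) {
    out <- data.frame(gene_id = integer(0), symbol = character(0),
                      count = integer(0), directions = character(0),
                      concordant = logical(0),
                      consensus_direction = character(0),
                      studies = character(0), stringsAsFactors = FALSE)
    class(out) <- c("vote_table", "data.frame")
    return(out)
  }
  sp <- split(collection, collection$gene_id)
  rows <- lapply(sp, function(d) {
    d <- d[order(d$study_id), , drop = FALSE]
    dirs <- unique(d$direction)
    data.frame(gene_id = d$gene_id[1], symbol = d$symbol[1],
               count = nrow(d),
               directions = paste(d$direction, collapse = ","),
               concordant = length(dirs) == 1,
               consensus_direction = if (length(dirs) == 1) dirs else NA_character_,
               studies = paste(d$study_id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(-out$count, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vote_table", "data.frame")
  out
}

#' Select candidate marker genes from a vote table
#'
#' @param table a [tally_votes()] result.
#' @param min_count minimum number of supporting studies (>= 1).
#' @param concordant_only drop genes whose reported directions disagree
#'   across studies (such genes never acquire a consensus direction).
#' @return The filtered `vote_table`, in the table's deterministic order.
#' @export
select_candidates <- function(table, min_count = 2, concordant_only = TRUE) {
  stopifnot(inherits(table, "vote_table"))
  if (min_count < 1) stop("'min_count' must be >= 1")
  keep <- table$count >= min_count
  if (concordant_only) keep <- keep & table$concordant
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Published per-study gene reports for the FTC/FTA meta-analysis corpus
#'
#' Loads the packaged reconstruction of the cross-study gene reports
#' underlying the 14-study follicular thyroid tumor meta-analysis: one record
#' per (study, gene) pair for every gene reported by two or more studies,
#' with Entrez id, symbol and direction of change relative to FTC. Feeding
#' this collection to [tally_votes()] reproduces the published tally (seven
#' genes reported by three studies, all down-regulated in FTC).
#'
#' @return A canonical `study_collection` data frame.
#' @export
meta_study_reports <- function() {
  path <- system.file("extdata", "ftc_fta_meta_gene_reports.tsv",
                      package = "folliclass", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$gene_id <- as.integer(d$gene_id)
  d <- d[order(d$study_id, d$gene_id), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("study_collection", "data.frame")
  d
}
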