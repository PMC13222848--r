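# Reading, validation and tree-matching of karyotype tables.
#
# A karyotype record is one literature report for a species: its haploid
# autosome count and sex chromosome system (SCS). Species may carry several
# conflicting records; downstream MCMC resolves them by a fresh uniform draw
# per run.

.scs_levels <- c("XY", "XO", "neoXY")

# Normalize the sex-chromosome-system vocabulary seen in cytogenetic
# literature. "Xyp" (distance-pairing punctiform y) is an XY system;
# spelling variants of neo-XY collapse to "neoXY".
normalize_scs <- function(x) {
  x <- gsub("[ _-]", "", as.character(x))
  out <- rep(NA_character_, length(x))
  lx <- tolower(x)
  out[lx %in% c("xy", "xyp", "xxy", "xyr")] <- "XY"
  out[lx %in% c("xo", "x0", "xxo")] <- "XO"
  out[lx %in% c("neoxy", "nxy")] <- "neoXY"
  out
}

normalize_species <- function(x) {
  x <- trimws(as.character(x))
  gsub("\\s+", "_", x)
}

#' Read a karyotype table
#'
#' Reads a delimited text table with (case-insensitive) columns `species`,
#' `haploid_autosomes` and `scs`, plus an optional `source` column.
#' Duplicate species are allowed and represent multiple conflicting records
#' for the same tip. SCS labels are normalized (`"neo-XY"`, `"Xyp"`, ...);
#' labels outside \{XY, XO, neoXY\} — e.g. multi-sex-chromosome systems such
#' as `X1X2Y` — are rejected.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param sep Field separator, `","` or `"\t"`.
#' @return A `data.frame` with columns `species`, `haploid_autosomes`,
#'   `scs` and `source`, one row per record.
#' @export
read_karyotype_table <- function(path, sep = ",") {
  stopifnot(file.exists(path))
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  aliases <- list(
    species = c("species", "taxon", "tip", "name"),
    haploid_autosomes = c("haploid_autosomes", "haploid_autosome_number",
                          "autosomes", "n_autosomes", "k"),
    scs = c("scs", "sex_chromosome_system", "system"))
  cols <- lapply(aliases, function(a) {
    hit <- intersect(a, names(raw))
    if (length(hit) == 0) NA_character_ else hit[1]
  })
  missing <- names(cols)[vapply(cols, is.na, logical(1))]
  if (length(missing) > 0) {
    stop("karyotype table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("karyotype table ", path, " has a header but no records")
    return(data.frame(species = character(), haploid_autosomes = integer(),
                      scs = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  rec <- data.frame(
    species = normalize_species(raw[[cols$species]]),
    haploid_autosomes = raw[[cols$haploid_autosomes]],
    scs_raw = as.character(raw[[cols$scs]]),
    source = if ("source" %in% names(raw)) as.character(raw$source)
             else NA_character_,
    stringsAsFactors = FALSE)

  k_num <- suppressWarnings(as.numeric(rec$haploid_autosomes))
  bad_k <- which(is.na(k_num) | k_num < 1 | k_num != round(k_num))
  if (length(bad_k) > 0) {
    stop("invalid haploid autosome count in row(s) ",
         paste(bad_k, collapse = ", "),
         " (must be a positive integer)", call. = FALSE)
  }
  rec$haploid_autosomes <- as.integer(k_num)

  rec$scs <- normalize_scs(rec$scs_raw)
  bad_s <- which(is.na(rec$scs))
  if (length(bad_s) > 0) {
    stop("unsupported sex chromosome system ",
         paste(unique(rec$scs_raw[bad_s]), collapse = ", "),
         " in row(s) ", paste(bad_s, collapse = ", "),
         " (supported: XY, XO, neoXY)", call. = FALSE)
  }
  bad_sp <- which(!nzchar(rec$species))
  if (length(bad_sp) > 0) {
    stop("empty species name in row(s) ", paste(bad_sp, collapse = ", "),
         call. = FALSE)
  }
  rec$scs_raw <- NULL
  rec
}

#' Write a karyotype table
#'
#' Inverse of [read_karyotype_table()]; round-trips records exactly.
#'
#' @param records Record data frame as returned by [read_karyotype_table()].
#' @param path Output file path.
#' @export
write_karyotype_table <- function(records, path) {
  write.csv(records[, c("species", "haploid_autosomes", "scs", "source")],
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read phylogenies from a Newick or Nexus file
#'
#' All trees must be rooted with branch lengths; duplicate tip labels within
#' a tree are an error. Returns a `multiPhylo` list (also for a single tree).
#'
#' @param path Tree file; format detected from content (`#NEXUS` header).
#' @return A `multiPhylo` object.
#' @export
read_trees <- function(path) {
  stopifnot(file.exists(path))
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  trees <- if (startsWith(first, "#NEXUS")) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  if (is.null(trees) || length(trees) == 0) {
    stop("no trees could be parsed from ", path, call. = FALSE)
  }
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (is.null(tr$edge.length)) {
      stop("tree ", i, " has no branch lengths", call. = FALSE)
    }
    if (any(tr$edge.length < 0)) {
      stop("tree ", i, " has negative branch lengths", call. = FALSE)
    }
    if (anyDuplicated(tr$tip.label) > 0) {
      stop("tree ", i, " has duplicate tip labels: ",
           paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                 collapse = ", "), call. = FALSE)
    }
    trees[[i]]$tip.label <- normalize_species(tr$tip.label)
  }
  message(length(trees), " tree(s) read from ", path)
  trees
}

#' Match karyotype records to tree tips
#'
#' For each tree, prunes tips without any karyotype record and drops records
#' whose species is absent from the tree; both sets are reported. Matching is
#' exact after whitespace/underscore normalization.
#'
#' @param trees A `multiPhylo` (or single `phylo`).
#' @param records Karyotype record data frame.
#' @return A list of matched datasets, each a list with elements `tree`
#'   (pruned `phylo`) and `records` (rows for retained tips).
#' @export
match_tips <- function(trees, records) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  stopifnot(length(trees) >= 1, nrow(records) >= 1)
  lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    keep <- intersect(tr$tip.label, records$species)
    if (length(keep) == 0) {
      stop("tree ", i, ": no overlap between tree tips and karyotype records",
           call. = FALSE)
    }
    dropped_tips <- setdiff(tr$tip.label, keep)
    dropped_recs <- setdiff(unique(records$species), keep)
    if (length(dropped_tips) > 0) {
      message("tree ", i, ": pruned ", length(dropped_tips),
              " tip(s) without karyotype data: ",
              paste(dropped_tips, collapse = ", "))
    }
    if (length(dropped_recs) > 0 && i == 1) {
      message("dropped ", length(dropped_recs),
              " record species absent from the tree")
    }
    pruned <- if (length(dropped_tips) > 0) ape::keep.tip(tr, keep) else tr
    list(tree = pruned,
         records = records[records$species %in% keep, , drop = FALSE])
  })
}

#' Resolve conflicting tip records to one state per tip
#'
#' Tips with multiple conflicting karyotype records get one record drawn
#' uniformly at random; tips with a single record keep it. Each MCMC
#' replicate calls this with a fresh seed so tip-state uncertainty is
#' propagated into the pooled posterior.
#'
#' @param dataset A matched dataset (element of [match_tips()] output).
#' @param seed Integer seed; the draw is reproducible.
#' @return Data frame with one row per tip: `species`, `haploid_autosomes`,
#'   `scs`.
#' @export
resolve_tip_states <- function(dataset, seed) {
  recs <- dataset$records
  tips <- dataset$tree$tip.label
  stopifnot(all(tips %in% recs$species))
  set.seed(as.integer(seed))
  out <- lapply(tips, function(sp) {
    rows <- which(recs$species == sp)
    pick <- if (length(rows) == 1) rows else rows[sample.int(length(rows), 1)]
    recs[pick, c("species", "haploid_autosomes", "scs")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
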