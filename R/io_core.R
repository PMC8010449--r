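#' Construct an abundance matrix
#'
#' An abundance matrix holds specimen counts per stratigraphic level (rows,
#' ordered oldest first, i.e. stratigraphically lowest first) and taxon
#' (columns). Each level has a thickness in centimetres (10 cm for raw field
#' data).
#'
#' @param counts Non-negative integer matrix, rows = levels, columns = taxa.
#'   Column names are taken as taxon names and must be unique.
#' @param level_ids Identifiers per level, oldest first. Defaults to row names
#'   of `counts` or `1..L`.
#' @param thickness_cm Level thickness in cm, recycled to one value per level.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(counts, level_ids = NULL, thickness_cm = 10) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("taxon_", seq_len(ncol(counts)))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate taxon names: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(!is.finite(counts) | counts < 0 |
                   abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("counts must be non-negative integers; offending cell row %d, column '%s'",
                 bad[1], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  if (is.null(level_ids)) {
    level_ids <- rownames(counts)
    if (is.null(level_ids)) level_ids <- as.character(seq_len(nrow(counts)))
  }
  if (length(level_ids) != nrow(counts)) {
    stop("level_ids length must equal number of rows")
  }
  thickness_cm <- rep_len(as.numeric(thickness_cm), nrow(counts))
  if (any(thickness_cm <= 0)) stop("thickness_cm must be positive")
  rownames(counts) <- as.character(level_ids)
  structure(
    list(counts = counts, level_ids = as.character(level_ids),
         thickness_cm = thickness_cm),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d levels x %d taxa, %d specimens, %.0f cm span\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              sum(x$thickness_cm)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$counts)

taxa_of <- function(m) colnames(m$counts)

#' Read a stratigraphic abundance table
#'
#' Parses a CSV whose first column is the level identifier/depth (rows ordered
#' oldest, i.e. lowest, first) and remaining columns are per-taxon specimen
#' counts, as in the deposited `abundance.csv` layout.
#'
#' @param path Path to a CSV file.
#' @param thickness_cm Level thickness in cm (default 10, the field
#'   resolution).
#' @return An [abundance_matrix()].
#' @export
read_abundance_table <- function(path, thickness_cm = 10) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance table needs a level column plus taxa")
  taxa <- names(df)[-1]
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon header: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(counts)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric counts in column '%s'", taxa[bad]))
  }
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at row %d ('%s'), column '%s'",
                 bad[1, 1], df[[1]][bad[1, 1]], taxa[bad[1, 2]]))
  }
  abundance_matrix(counts, level_ids = as.character(df[[1]]),
                   thickness_cm = thickness_cm)
}

#' Write an abundance table
#'
#' Inverse of [read_abundance_table()]; round-trips losslessly.
#'
#' @param m An [abundance_matrix()].
#' @param path Output CSV path.
#' @export
write_abundance_table <- function(m, path) {
  df <- data.frame(level = m$level_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(m$counts, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

body_type_levels <- c("soft", "intermediate", "hard")
size_class_levels <- c("small", "medium", "large")
habitat_levels <- c("endo/epibenthic", "nektobenthic", "nektonic/pelagic")

#' Construct a taxon trait table
#'
#' Four ecological/taphonomic labels per taxon: body type (soft /
#' intermediate / hard), maximum body size class (small < 15 cm, medium
#' 15-30 cm, large > 30 cm), habitat (endo/epibenthic, nektobenthic,
#' nektonic/pelagic) and a free categorical motility class.
#'
#' @param taxon Character vector of taxon names (unique).
#' @param body_type,size_class,habitat,motility Per-taxon labels.
#' @return A `taxon_traits` data frame keyed by taxon.
#' @export
taxon_traits <- function(taxon, body_type, size_class, habitat, motility) {
  taxon <- as.character(taxon)
  if (anyDuplicated(taxon)) stop("duplicate taxon in trait table")
  check_levels <- function(x, allowed, what) {
    x <- as.character(x)
    bad <- setdiff(unique(x), allowed)
    if (length(bad) > 0) {
      stop(sprintf("unrecognized %s value(s) %s; allowed: %s", what,
                   paste(sQuote(bad), collapse = ", "),
                   paste(allowed, collapse = ", ")))
    }
    x
  }
  motility <- as.character(motility)
  if (any(is.na(motility) | motility == "")) stop("missing motility label")
  out <- data.frame(
    taxon = taxon,
    body_type = check_levels(body_type, body_type_levels, "body_type"),
    size_class = check_levels(size_class, size_class_levels, "size_class"),
    habitat = check_levels(habitat, habitat_levels, "habitat"),
    motility = motility,
    stringsAsFactors = FALSE
  )
  class(out) <- c("taxon_traits", "data.frame")
  out
}

#' Read a taxon trait table
#'
#' CSV with columns `taxon`, `body_type`, `size_class`, `habitat`,
#' `motility` (the `metadata_traits.csv` layout). Unknown category strings
#' are rejected, never coerced.
#'
#' @param path Path to a CSV file.
#' @return A [taxon_traits()] table.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("taxon", "body_type", "size_class", "habitat", "motility")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  taxon_traits(df$taxon, df$body_type, df$size_class, df$habitat, df$motility)
}

#' Write a taxon trait table
#' @param traits A [taxon_traits()] table.
#' @param path Output CSV path.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Look up one trait factor for a set of taxa
#'
#' @param traits A [taxon_traits()] table.
#' @param taxa Taxon names; all must be present.
#' @param factor One of `"body_type"`, `"size_class"`, `"habitat"`,
#'   `"motility"`.
#' @return Named character vector of labels.
#' @export
trait_labels <- function(traits, taxa,
                         factor = c("body_type", "size_class", "habitat",
                                    "motility")) {
  factor <- match.arg(factor)
  idx <- match(taxa, traits$taxon)
  if (anyNA(idx)) {
    stop("taxa missing from trait table: ",
         paste(taxa[is.na(idx)], collapse = ", "))
  }
  stats::setNames(traits[[factor]][idx], taxa)
}

#' Aggregate stratigraphic levels into thicker bins
#'
#' Consecutive levels are summed into bins of `bin_cm`; trailing levels that
#' do not fill a whole bin are dropped (9.3 m of 10 cm levels at
#' `bin_cm = 20` gives 46 bins). Counts are conserved over the retained span.
#'
#' @param m An [abundance_matrix()].
#' @param bin_cm Bin thickness; must be an integer multiple of the (uniform)
#'   input thickness.
#' @return A binned [abundance_matrix()].
#' @export
bin_levels <- function(m, bin_cm) {
  thick <- unique(m$thickness_cm)
  if (length(thick) != 1) stop("bin_levels requires uniform level thickness")
  ratio <- bin_cm / thick
  if (abs(ratio - round(ratio)) > 1e-8 || ratio < 1) {
    stop(sprintf("bin_cm (%s) must be a positive integer multiple of level thickness (%s)",
                 bin_cm, thick))
  }
  ratio <- as.integer(round(ratio))
  n_bins <- nrow(m$counts) %/% ratio
  if (n_bins == 0) stop("bin_cm exceeds the stratigraphic span")
  keep <- seq_len(n_bins * ratio)
  grp <- rep(seq_len(n_bins), each = ratio)
  binned <- rowsum(m$counts[keep, , drop = FALSE], grp, reorder = FALSE)
  ids <- vapply(split(m$level_ids[keep], grp), function(v) v[1], character(1))
  abundance_matrix(binned, level_ids = unname(ids), thickness_cm = bin_cm)
}

#' Build running (sliding) stratigraphic windows
#'
#' Contiguous windows of `width` levels advancing by `step` levels; the
#' number of windows is `floor((L - width) / step) + 1`.
#'
#' @param m An [abundance_matrix()].
#' @param width Window width in levels; must not exceed the number of levels.
#' @param step Advance between window starts, in levels.
#' @return A `strat_windows` data frame with columns `window_id`, `start`,
#'   `end` (level indices, inclusive) and `depth_span_cm`.
#' @export
make_windows <- function(m, width = 8, step = 1) {
  L <- nrow(m$counts)
  width <- as.integer(width); step <- as.integer(step)
  if (width < 1 || step < 1) stop("width and step must be positive integers")
  if (width > L) stop(sprintf("width (%d) exceeds number of levels (%d)", width, L))
  starts <- seq.int(1L, L - width + 1L, by = step)
  out <- data.frame(
    window_id = seq_along(starts),
    start = starts,
    end = starts + width - 1L
  )
  out$depth_span_cm <- vapply(seq_len(nrow(out)), function(i) {
    sum(m$thickness_cm[out$start[i]:out$end[i]])
  }, numeric(1))
  class(out) <- c("strat_windows", "data.frame")
  out
}

#' Subset an abundance matrix to a window
#' @param m An [abundance_matrix()].
#' @param window One row of a [make_windows()] result (or a list with
#'   `start`/`end`).
#' @return The [abundance_matrix()] restricted to the window's levels.
#' @export
window_slice <- function(m, window) {
  idx <- window$start:window$end
  abundance_matrix(m$counts[idx, , drop = FALSE],
                   level_ids = m$level_ids[idx],
                   thickness_cm = m$thickness_cm[idx])
}

#' Construct a correlation network
#'
#' Undirected signed network over taxa; edges carry the (partial) correlation
#' as weight plus the BH-adjusted q-value that admitted them.
#'
#' @param nodes Character vector of taxon names.
#' @param edges Data frame with columns `taxon_a`, `taxon_b`, `weight`,
#'   `q_value` (possibly zero rows).
#' @return An object of class `corr_network`.
#' @export
corr_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(taxon_a = character(0), taxon_b = character(0),
                        weight = numeric(0), q_value = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(taxon_a = as.character(edges$taxon_a),
                        taxon_b = as.character(edges$taxon_b),
                        weight = as.numeric(edges$weight),
                        q_value = as.numeric(edges$q_value),
                        stringsAsFactors = FALSE)
    if (any(edges$taxon_a == edges$taxon_b)) {
      stop("self-loop edge not allowed")
    }
    if (!all(c(edges$taxon_a, edges$taxon_b) %in% nodes)) {
      stop("edge endpoint not in node set")
    }
    # canonical orientation so that round-trips and comparisons are stable
    swap <- edges$taxon_a > edges$taxon_b
    tmp <- edges$taxon_a[swap]
    edges$taxon_a[swap] <- edges$taxon_b[swap]
    edges$taxon_b[swap] <- tmp
    key <- paste(edges$taxon_a, edges$taxon_b, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edge")
    edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("corr_network: %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight > 0),
              sum(x$edges$weight < 0)))
  invisible(x)
}

#' Write a correlation network as an edge-list CSV
#'
#' Columns exactly `taxon_a, taxon_b, weight, q_value`; the node set is kept
#' in a commented header line so that isolated nodes survive the round trip.
#'
#' @param g A [corr_network()].
#' @param path Output path.
#' @export
write_network <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes: ", paste(g$nodes, collapse = ";")), con)
  utils::write.csv(g$edges, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a correlation network edge-list CSV
#' @param path Path written by [write_network()].
#' @return A [corr_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  nodes <- character(0)
  if (length(lines) > 0 && startsWith(lines[1], "# nodes:")) {
    spec <- sub("^# nodes: ?", "", lines[1])
    if (nzchar(spec)) nodes <- strsplit(spec, ";", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("taxon_a", "taxon_b", "weight", "q_value")
  if (!all(need %in% names(df))) {
    stop("network file must have columns: ", paste(need, collapse = ", "))
  }
  if (length(nodes) == 0) nodes <- sort(unique(c(df$taxon_a, df$taxon_b)))
  if (nrow(df) > 0 && any(df$taxon_a == df$taxon_b)) {
    stop("self-loop edge in network file")
  }
  corr_network(nodes, df)
}
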