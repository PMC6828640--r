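#' Dyadic dataset of paired semicontinuous reports
#'
#' A long-format data frame with exactly two rows per dyad (one per rater
#' role) and columns `dyad_id`, `role` (`"gambler"`/`"cso"`), `group`
#' (relationship of the CSO to the gambler), `y` (non-negative amount per
#' day) and optionally `signup_date`. A `metadata` attribute carries the
#' provenance log of any filters applied on ingest.
#'
#' @param df data frame with the columns above.
#' @param metadata optional list of provenance entries.
#' @return object of classes `dyad_data` and `data.frame`.
#' @export
dyad_data <- function(df, metadata = list()) {
  req <- c("dyad_id", "role", "group", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$role <- as.character(df$role)
  df$group <- as.character(df$group)
  bad_role <- setdiff(unique(df$role), c("gambler", "cso"))
  if (length(bad_role)) stop("unknown role label(s): ", paste(bad_role, collapse = ", "))
  if (any(is.na(df$y)) || any(df$y < 0)) stop("y must be non-negative and non-missing")
  tab <- table(df$dyad_id, df$role)
  if (!all(tab == 1L)) {
    stop("every dyad_id must appear exactly twice, once per role")
  }
  grp_per_dyad <- tapply(df$group, df$dyad_id, function(g) length(unique(g)))
  if (any(grp_per_dyad != 1L)) stop("group must be identical within a dyad")
  rownames(df) <- NULL
  structure(as.data.frame(df), metadata = metadata,
            class = c("dyad_data", "data.frame"))
}

#' @export
print.dyad_data <- function(x, ...) {
  nd <- length(unique(x$dyad_id))
  cat(sprintf("Dyadic dataset: %d dyads (%d reports)\n", nd, nrow(x)))
  print(dyad_counts(x))
  md <- attr(x, "metadata")
  if (length(md)) {
    cat("Filters applied:\n")
    for (m in md) cat("  -", format_filter_entry(m), "\n")
  }
  invisible(x)
}

format_filter_entry <- function(m) {
  if (is.list(m)) sprintf("%s: removed %d dyad(s)", m$filter, m$removed)
  else as.character(m)
}

#' Number of dyads per relationship group
#'
#' @param data a [dyad_data] object.
#' @return named integer vector of dyad counts.
#' @export
dyad_counts <- function(data) {
  one <- data[data$role == "gambler", ]
  tab <- table(one$group)
  stats::setNames(as.integer(tab), names(tab))
}

#' Reshape a dyadic dataset to one row per dyad
#'
#' @param data a [dyad_data] object.
#' @return data frame with columns `dyad_id`, `group`, `y_gambler`, `y_cso`.
#' @export
dyad_wide <- function(data) {
  g <- data[data$role == "gambler", c("dyad_id", "group", "y")]
  c <- data[data$role == "cso", c("dyad_id", "y")]
  names(g)[3] <- "y_gambler"
  names(c)[2] <- "y_cso"
  out <- merge(g, c, by = "dyad_id", sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Write a dyadic dataset as long-format CSV
#'
#' Numeric columns are written at full precision so that reading the file
#' back with [read_dyads()] reproduces them bit-exactly.
#'
#' @param data a [dyad_data] object.
#' @param path output file path.
#' @export
write_dyads <- function(data, path) {
  df <- as.data.frame(data)
  df$y <- sprintf("%.17g", df$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
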