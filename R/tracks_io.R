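#' @importFrom stats aggregate as.formula coef lm logLik median model.matrix
#'   pnorm predict quantile rbinom resid rnorm runif sd setNames terms vcov
#'   delete.response kmeans complete.cases pchisq rmultinom sigma uniroot
#' @importFrom utils head read.csv write.csv
NULL

# canonical Movebank-style column names
.movebank_dialect <- c(
  id  = "individual-local-identifier",
  t   = "timestamp",
  lon = "location-long",
  lat = "location-lat"
)

new_track_set <- function(fixes, provenance = list()) {
  structure(list(fixes = fixes, provenance = provenance),
            class = "track_set")
}

#' Read a Movebank-style tracking CSV
#'
#' Ingests GPS fixes (one row per location), maps dialect column names onto
#' the canonical `id`, `t`, `lon`, `lat`, parses timestamps as UTC, sorts
#' each individual by time, and removes duplicate `(id, t)` records.
#' Malformed rows are never silently dropped: every reject is logged with
#' its input row number and a reason, and the provenance satisfies
#' `rows_in == rows_kept + rows_rejected`.
#'
#' @param path Path to a CSV file.
#' @param dialect Named character vector mapping the canonical names
#'   (`id`, `t`, `lon`, `lat`) to the file's column names. Defaults to the
#'   Movebank export names (`individual-local-identifier`, `timestamp`,
#'   `location-long`, `location-lat`).
#' @return A `track_set`: list with `fixes` (data.frame `id`, `t`, `lon`,
#'   `lat`) and `provenance` (source, row counts, reject log).
#' @export
read_tracks <- function(path, dialect = .movebank_dialect) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(dialect[c("id", "t", "lon", "lat")]),
                          names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    id  = as.character(raw[[dialect[["id"]]]]),
    lon = suppressWarnings(as.numeric(raw[[dialect[["lon"]]]])),
    lat = suppressWarnings(as.numeric(raw[[dialect[["lat"]]]])),
    stringsAsFactors = FALSE
  )
  df$t <- parse_utc(as.character(raw[[dialect[["t"]]]]))
  as_track_set(df, source = path)
}

#' Build a track set from an in-memory data frame
#'
#' Applies the same ordering, validation and de-duplication rules as
#' [read_tracks()].
#'
#' @param df Data frame with columns `id`, `t` (POSIXct UTC), `lon`, `lat`.
#' @param source Provenance label.
#' @return A `track_set`.
#' @export
as_track_set <- function(df, source = "memory") {
  stopifnot(all(c("id", "t", "lon", "lat") %in% names(df)))
  df <- df[, c("id", "t", "lon", "lat")]
  n_in <- nrow(df)
  reason <- rep(NA_character_, n_in)
  reason[is.na(df$t)] <- "unparseable timestamp"
  bad_coord <- is.na(reason) &
    (!is.finite(df$lon) | !is.finite(df$lat) |
       abs(df$lon) > 180 | abs(df$lat) > 90)
  reason[bad_coord] <- "invalid coordinate"
  reason[is.na(reason) & (is.na(df$id) | df$id == "")] <- "missing id"
  keep <- is.na(reason)
  kept <- df[keep, , drop = FALSE]
  kept_row <- which(keep)
  o <- order(kept$id, kept$t)
  kept <- kept[o, , drop = FALSE]
  kept_row <- kept_row[o]
  dup <- duplicated(kept[, c("id", "t")])
  if (any(dup)) reason[kept_row[dup]] <- "duplicate (id, t)"
  kept <- kept[!dup, , drop = FALSE]
  rownames(kept) <- NULL
  rejects <- data.frame(row = which(!is.na(reason)),
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  new_track_set(kept, provenance = list(
    source = source, rows_in = n_in,
    rows_kept = nrow(kept), rows_rejected = nrow(rejects),
    rejects = rejects))
}

parse_utc <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", "", x)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  miss <- is.na(out) & !is.na(x)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = "%Y-%m-%d %H:%M")
  }
  out
}

#' Write a track set as Movebank-style CSV
#'
#' @param tracks A `track_set`.
#' @param path Output CSV path.
#' @param dialect Column-name mapping, as in [read_tracks()].
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, dialect = .movebank_dialect) {
  fx <- tracks$fixes
  out <- data.frame(
    a = fx$id,
    b = format(fx$t, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    c = fx$lon,
    d = fx$lat,
    check.names = FALSE
  )
  names(out) <- unname(dialect[c("id", "t", "lon", "lat")])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.track_set <- function(x, ...) {
  p <- x$provenance
  cat("<track_set> ", length(unique(x$fixes$id)), " individuals, ",
      nrow(x$fixes), " fixes", sep = "")
  if (!is.null(p$rows_in)) {
    cat(" (", p$rows_in, " rows in, ", p$rows_rejected, " rejected)", sep = "")
  }
  cat("\n")
  invisible(x)
}

# list of per-individual fix data.frames, time-ordered
split_tracks <- function(tracks) {
  split(tracks$fixes, tracks$fixes$id)
}
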