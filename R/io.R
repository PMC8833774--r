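# Delimited-text interchange formats. All files are UTF-8, tab-separated with
# a header row, "." decimal separator, and "#"-prefixed metadata lines before
# the header.

default_event_schema <- c(event_id = "event_id", record_type = "record_type",
                          strand = "strand", base = "base",
                          energy_eV = "energy_eV")

read_meta_lines <- function(path, n = 50L) {
  lines <- readLines(path, n = n, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    hit <- regmatches(m, regexec("^#\\s*([A-Za-z_]+)\\s*[:=]\\s*(.*)$", m))[[1]]
    if (length(hit) == 3L) meta[[hit[2]]] <- trimws(hit[3])
  }
  list(meta = meta, n_meta = length(grep("^#", lines)))
}

#' Write and read scored-event files
#'
#' Tab-separated text with one row per interaction or OH hit: columns
#' `event_id`, `record_type` (`EDEP`/`OH`), `strand`, `base`, `energy_eV`
#' (empty for OH rows). Metadata (`n_decays`, `n_bases`, `label`) is stored in
#' `#`-prefixed lines so that decays without records survive a round trip.
#' Energy deposits below 0.25 eV are accepted on read but reported, since the
#' damage models treat them as negligible.
#'
#' @param dataset A [track_dataset()].
#' @param path File path.
#' @param schema Named character vector mapping the canonical column names
#'   (`event_id`, `record_type`, `strand`, `base`, `energy_eV`) to the column
#'   names used in the file.
#' @param n_decays,n_bases Overrides for the file metadata; when neither the
#'   file nor the caller supplies them, `n_decays` is inferred as
#'   `max(event_id) + 1` and `n_bases` defaults to 40.
#' @return `read_scored_events()` returns a [track_dataset()];
#'   `write_scored_events()` invisibly returns `path`.
#' @export
write_scored_events <- function(dataset, path) {
  stopifnot(inherits(dataset, "track_dataset"))
  writeLines(c(
    "# iodamage scored events v1",
    sprintf("# n_decays: %d", dataset$n_decays),
    sprintf("# n_bases: %d", dataset$n_bases),
    sprintf("# label: %s", dataset$label)
  ), path, useBytes = TRUE)
  readr::write_tsv(dataset$records, path, na = "", col_names = TRUE,
                   append = TRUE)
  invisible(path)
}

#' @rdname write_scored_events
#' @export
read_scored_events <- function(path, schema = NULL, n_decays = NULL,
                               n_bases = NULL) {
  schema <- if (is.null(schema)) default_event_schema
             else c(default_event_schema[setdiff(names(default_event_schema),
                                                 names(schema))], schema)
  hdr <- read_meta_lines(path)
  df <- readr::read_tsv(path, comment = "#", na = c("", "NA"),
                        show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(unname(schema), names(df))
  if (length(missing)) {
    abort(paste0("event file is missing columns: ", paste(missing, collapse = ", ")))
  }
  df <- setNames(df[unname(schema)], names(schema))
  line_offset <- hdr$n_meta + 1L # metadata lines + header row
  num <- function(col, what, integer = TRUE) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !(col == "energy_eV" & df$record_type == "OH") &
                   !is.na(df[[col]]) | (is.na(df[[col]]) & col != "energy_eV"))
    if (length(bad)) {
      abort(sprintf("cannot parse %s at line %d", what, bad[1] + line_offset))
    }
    if (integer) as.integer(x) else x
  }
  records <- tibble::tibble(
    event_id = num("event_id", "event_id"),
    record_type = df$record_type,
    strand = num("strand", "strand"),
    base = num("base", "base"),
    energy_eV = num("energy_eV", "energy_eV", integer = FALSE)
  )
  n_decays <- n_decays %||%
    (if (!is.null(hdr$meta$n_decays)) as.integer(hdr$meta$n_decays)
     else if (nrow(records)) max(records$event_id) + 1L else 0L)
  n_bases <- n_bases %||%
    (if (!is.null(hdr$meta$n_bases)) as.integer(hdr$meta$n_bases) else 40L)
  label <- hdr$meta$label %||% ""
  validate_records(records, n_decays, n_bases, line_offset = line_offset)
  n_sub <- sum(records$record_type == "EDEP" & records$energy_eV < 0.25,
               na.rm = TRUE)
  if (n_sub > 0) {
    rlang::inform(sprintf(
      "%d energy deposits below 0.25 eV kept; they are negligible for damage calling.",
      n_sub))
  }
  track_dataset(records, n_decays = n_decays, n_bases = n_bases, label = label)
}

#' Write and read fragment-distribution files
#'
#' Tab-separated text with columns `site` (0-based break-site index; the
#' unbroken class, when present, is written as an empty site) and `fraction`.
#' The normalisation mode is recorded in a `# mode:` metadata line.
#'
#' @param f A [fragment_distribution()] (or a tibble with `site`/`fraction`).
#' @param path File path.
#' @param scavenging Optional scavenging condition (`"high"` or `"low"`)
#'   recorded for observed experimental data.
#' @return `read_fragment_distribution()` returns a [fragment_distribution()];
#'   `write_fragment_distribution()` invisibly returns `path`.
#' @export
write_fragment_distribution <- function(f, path) {
  mode <- attr(f, "mode") %||% "breaks_only"
  scav <- attr(f, "scavenging")
  writeLines(c("# iodamage fragment distribution v1",
               sprintf("# mode: %s", mode),
               if (!is.null(scav)) sprintf("# scavenging: %s", scav)),
             path, useBytes = TRUE)
  readr::write_tsv(tibble::tibble(site = f$site, fraction = f$fraction),
                   path, na = "", col_names = TRUE, append = TRUE)
  invisible(path)
}

#' @rdname write_fragment_distribution
#' @export
read_fragment_distribution <- function(path, scavenging = NULL) {
  hdr <- read_meta_lines(path)
  df <- readr::read_tsv(path, comment = "#", na = c("", "NA"),
                        show_col_types = FALSE,
                        col_types = readr::cols(site = readr::col_integer(),
                                                fraction = readr::col_double()))
  fragment_distribution_tbl(
    df$site, df$fraction,
    mode = hdr$meta$mode %||% "breaks_only",
    scavenging = scavenging %||% hdr$meta$scavenging
  )
}

#' Export break calls as delimited text
#'
#' One row per broken site: `event_id`, `strand`, `base`, `cause`.
#'
#' @param call A [break_calls()] object.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_break_calls <- function(call, path) {
  stopifnot(inherits(call, "break_calls"))
  writeLines(c("# iodamage break calls v1",
               sprintf("# n_decays: %d", call$n_decays),
               sprintf("# n_bases: %d", call$n_bases)), path, useBytes = TRUE)
  readr::write_tsv(call$breaks, path, col_names = TRUE, append = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
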