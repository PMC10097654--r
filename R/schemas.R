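#' Ordinal fragment health categories
#'
#' The five visual scoring categories used for replicate fragments, in
#' increasing order of severity. Their position (1-5) supplies the weights
#' of the bleaching and mortality index, so the order is load-bearing.
#'
#' @return Character vector of the five category labels, healthy first.
#' @export
#' @examples
#' health_levels()
health_levels <- function() {
  c("healthy", "half_bleached", "bleached", "partial_mortality", "dead")
}

# index 1..5 of a category vector; error on unknown labels
category_index <- function(category) {
  idx <- match(category, health_levels())
  if (anyNA(idx) && !all(is.na(category[is.na(idx)]))) {
    bad <- unique(category[is.na(idx) & !is.na(category)])
    stop_validation(sprintf(
      "unknown health category: %s (expected one of %s)",
      paste(bad, collapse = ", "), paste(health_levels(), collapse = ", ")
    ))
  }
  idx
}

stop_schema <- function(msg) {
  rlang::abort(msg, class = "coralheat_schema_error")
}

stop_validation <- function(msg) {
  rlang::abort(msg, class = "coralheat_validation_error")
}

# schema registry: required columns, column types, per-table invariant checks
coral_schemas <- function() {
  list(
    temperature = list(
      cols = c(tank_id = "c", timestamp = "T", temp_c = "d")
    ),
    health = list(
      cols = c(colony_id = "c", fragment_id = "c", tank_id = "c",
               survey_time = "T", category = "c")
    ),
    size = list(
      cols = c(colony_id = "c", survey_date = "D", diameter_cm = "d",
               sa_cm2 = "d", livesa_cm2 = "d", volume_cm3 = "d",
               partial_mortality = "l")
    ),
    dissection = list(
      cols = c(colony_id = "c", fragment_id = "c", polyp_index = "i",
               egg_count = "i", egg_diameters_mm = "c")
    ),
    symbiont = list(
      cols = c(colony_id = "c", its2_profile = "c", relative_abundance = "d")
    ),
    polyp_density = list(
      cols = c(colony_id = "c", polyps_per_cm2 = "d")
    )
  )
}

#' Names of the tabular schemas understood by the package
#' @return Character vector of schema names.
#' @export
schema_names <- function() names(coral_schemas())

#' Read and validate a study table
#'
#' Reads a delimited text file (comma for `.csv`, tab for `.tsv`) and
#' validates it against one of the package's schemas. Validation is total:
#' a missing column raises a schema error naming the column, and any row
#' violating a type invariant raises a validation error giving the row
#' index. Nothing is silently coerced.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema One of [schema_names()]: `"temperature"` (tank logger
#'   series), `"health"` (ordinal fragment scores), `"size"` (3D-model
#'   colony sizes), `"dissection"` (per-polyp egg counts and diameters),
#'   `"symbiont"` (ITS2 type-profile relative abundances), or
#'   `"polyp_density"`.
#' @return A validated tibble in file row order. The number of rows read is
#'   reported as a message.
#' @export
read_coral_table <- function(path, schema) {
  schema <- rlang::arg_match(schema, schema_names())
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  spec <- coral_schemas()[[schema]]
  raw <- readr::read_delim(path, delim = delim, na = character(),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(names(spec$cols), names(raw))
  if (length(missing) > 0) {
    stop_schema(sprintf("schema '%s': missing required column(s): %s",
                        schema, paste(missing, collapse = ", ")))
  }
  out <- convert_columns(raw[names(spec$cols)], spec$cols, schema)
  validate_coral_table(out, schema)
  message(sprintf("read %d %s record(s) from %s", nrow(out), schema, path))
  out
}

convert_columns <- function(df, cols, schema) {
  out <- df
  for (nm in names(cols)) {
    x <- df[[nm]]
    out[[nm]] <- switch(cols[[nm]],
      c = x,
      d = parse_strict(x, nm, schema, as.numeric),
      i = {
        v <- parse_strict(x, nm, schema, as.numeric)
        if (any(!is.na(v) & v != floor(v))) {
          stop_validation(sprintf("schema '%s': column '%s' must be integer-valued", schema, nm))
        }
        as.integer(v)
      },
      l = {
        lx <- tolower(trimws(x))
        v <- ifelse(lx %in% c("true", "t", "1"), TRUE,
                    ifelse(lx %in% c("false", "f", "0"), FALSE, NA))
        if (any(is.na(v) & !is.na(x) & x != "")) {
          stop_validation(sprintf("schema '%s': column '%s' must be logical", schema, nm))
        }
        as.logical(v)
      },
      D = {
        v <- as.Date(x, format = "%Y-%m-%d")
        if (anyNA(v)) stop_validation(sprintf("schema '%s': column '%s' must be ISO dates", schema, nm))
        v
      },
      T = {
        v <- as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d"))
        if (anyNA(v)) stop_validation(sprintf("schema '%s': column '%s' must be ISO timestamps", schema, nm))
        v
      }
    )
  }
  tibble::as_tibble(out)
}

parse_strict <- function(x, nm, schema, fn) {
  blank <- is.na(x) | x == ""
  v <- suppressWarnings(fn(x))
  bad <- which(is.na(v) & !blank)
  if (length(bad) > 0) {
    stop_validation(sprintf("schema '%s': column '%s' not numeric at row %d",
                            schema, nm, bad[1]))
  }
  v
}

#' Validate a study table against its schema invariants
#'
#' Checks the per-schema invariants (value ranges, ordering, closed
#' category sets, per-colony abundance sums, diameter-count consistency).
#' Called internally by [read_coral_table()]; exported so generated tables
#' can be checked directly.
#'
#' @param df A tibble with the schema's columns.
#' @param schema One of [schema_names()].
#' @return `df`, invisibly, if valid; otherwise a validation error naming
#'   the offending row.
#' @export
validate_coral_table <- function(df, schema) {
  schema <- rlang::arg_match(schema, schema_names())
  fail <- function(row, what) {
    stop_validation(sprintf("schema '%s': %s (row %d)", schema, what, row))
  }
  switch(schema,
    temperature = {
      bad <- which(df$temp_c < 20 | df$temp_c > 40)
      if (length(bad)) fail(bad[1], sprintf("temp_c %.2f outside [20, 40]", df$temp_c[bad[1]]))
      for (tk in unique(df$tank_id)) {
        ts <- df$timestamp[df$tank_id == tk]
        if (is.unsorted(ts, strictly = TRUE)) {
          fail(which(df$tank_id == tk)[which(diff(as.numeric(ts)) <= 0)[1] + 1],
               sprintf("timestamps not strictly increasing in tank %s", tk))
        }
      }
    },
    health = {
      bad <- which(!(df$category %in% health_levels()))
      if (length(bad)) fail(bad[1], sprintf("category '%s' not in the closed 5-level set", df$category[bad[1]]))
      dup <- duplicated(df[c("fragment_id", "survey_time")])
      if (any(dup)) fail(which(dup)[1], "fragment has more than one record at a survey_time")
    },
    size = {
      for (nm in c("sa_cm2", "livesa_cm2", "volume_cm3", "diameter_cm")) {
        bad <- which(!is.na(df[[nm]]) & df[[nm]] <= 0)
        if (length(bad)) fail(bad[1], sprintf("%s must be > 0 when present", nm))
      }
      bad <- which(df$livesa_cm2 > df$sa_cm2 + 1e-9)
      if (length(bad)) fail(bad[1], "livesa_cm2 exceeds sa_cm2")
    },
    dissection = {
      bad <- which(df$egg_count < 0)
      if (length(bad)) fail(bad[1], "egg_count must be >= 0")
      diam <- parse_egg_diameters(df$egg_diameters_mm)
      n_eggs <- vapply(diam, length, integer(1))
      bad <- which(n_eggs != df$egg_count)
      if (length(bad)) {
        fail(bad[1], sprintf("%d diameter entries for egg_count %d", n_eggs[bad[1]], df$egg_count[bad[1]]))
      }
      alld <- unlist(lapply(diam, unlist), use.names = FALSE)
      if (length(alld) && any(alld <= 0 | alld >= 2)) {
        bad <- which(vapply(diam, function(e) any(unlist(e) <= 0 | unlist(e) >= 2), logical(1)))
        fail(bad[1], "egg diameter outside (0, 2) mm")
      }
    },
    symbiont = {
      bad <- which(df$relative_abundance < 0 | df$relative_abundance > 1)
      if (length(bad)) fail(bad[1], "relative_abundance outside [0, 1]")
      sums <- tapply(df$relative_abundance, df$colony_id, sum)
      off <- which(abs(sums - 1) > 1e-6)
      if (length(off)) {
        colony <- names(sums)[off[1]]
        fail(which(df$colony_id == colony)[1],
             sprintf("abundances for colony %s sum to %.4f, not 1", colony, sums[off[1]]))
      }
    },
    polyp_density = {
      bad <- which(df$polyps_per_cm2 <= 0)
      if (length(bad)) fail(bad[1], "polyps_per_cm2 must be > 0")
    }
  )
  invisible(df)
}

#' Parse serialized egg diameters
#'
#' Dissection tables store each polyp's egg measurements in one cell:
#' eggs separated by `";"`, the two perpendicular axes of an egg by `"x"`
#' (e.g. `"0.58x0.61;0.55x0.60"`). An empty cell means zero eggs.
#'
#' @param x Character vector of serialized diameter cells.
#' @return A list, one element per polyp, each a list of numeric axis
#'   vectors (one per egg, in mm).
#' @export
parse_egg_diameters <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || cell == "") return(list())
    eggs <- strsplit(cell, ";", fixed = TRUE)[[1]]
    lapply(eggs, function(e) as.numeric(strsplit(e, "x", fixed = TRUE)[[1]]))
  })
}

serialize_egg_diameters <- function(diams) {
  vapply(diams, function(eggs) {
    if (length(eggs) == 0) return("")
    paste(vapply(eggs, function(ax) paste(formatC(ax, format = "fg", digits = 6), collapse = "x"),
                 character(1)), collapse = ";")
  }, character(1))
}

#' Write a study table or result table to CSV
#'
#' Writes records with a stable column order so that
#' `read_coral_table(write_coral_table(x))` is the identity on shared
#' schemas. Missing values are serialized as empty cells.
#'
#' @param df A non-empty data frame.
#' @param path Output path (`.csv` comma-delimited, `.tsv` tab-delimited).
#' @return `path`, invisibly.
#' @export
write_coral_table <- function(df, path) {
  if (!is.data.frame(df) || nrow(df) == 0) {
    stop_validation("refusing to write an empty record collection")
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  out <- df
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) {
      out[[nm]] <- format(out[[nm]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
    }
  }
  readr::write_delim(out, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}
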