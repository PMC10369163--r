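#' Read and write item-level CSV tables
#'
#' One file holds one instrument at one wave: a header of item identifiers
#' (`item1`, `item2`, ...) plus an `id` column, one row per participant.
#' Missing responses are empty fields.
#'
#' @param path File path.
#' @param instrument An [instrument_spec()].
#' @param wave Wave label attached to the returned table.
#' @return [read_item_csv()] returns an [item_response_table()];
#'   [write_item_csv()] returns `path` invisibly.
#' @export
read_item_csv <- function(path, instrument, wave = NA) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"id" %in% names(df))
    lcs_stop("item CSV must contain an 'id' column", "lcs_validation_error")
  item_cols <- setdiff(names(df), "id")
  item_response_table(df[item_cols], instrument, ids = df$id, wave = wave)
}

#' @rdname read_item_csv
#' @param items An [item_response_table()] to write.
#' @export
write_item_csv <- function(items, path) {
  df <- data.frame(id = items$ids, items$responses, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write wide trial tables
#'
#' The wide trial table is the package's universal exchange object: one row
#' per participant with columns `id`, `arm` (1 = treatment, 0 = control),
#' `sex`, and `<scale>_<wave>` score columns for waves 0-3 (e.g. `bdi_0`,
#' `bads_2`). Missing scores are empty fields in the CSV.
#'
#' @param path File path.
#' @return [read_trial_csv()] returns a data.frame; [write_trial_csv()]
#'   returns `path` invisibly.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "arm", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    lcs_stop(paste("trial CSV missing columns:", paste(miss, collapse = ", ")),
             "lcs_validation_error")
  if (!all(df$arm %in% c(0, 1)))
    lcs_stop("arm must be coded 0/1", "lcs_validation_error")
  df
}

#' @rdname read_trial_csv
#' @param table Wide trial data.frame.
#' @export
write_trial_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load or save an instrument registry as YAML
#'
#' The registry file maps instrument names to item counts, item ranges, and
#' severity bands, and round-trips through [instrument_spec()].
#'
#' @param path YAML file path.
#' @return [read_instrument_registry()] returns a named list of
#'   `instrument_spec` objects.
#' @export
read_instrument_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    bands <- if (!is.null(x$bands)) {
      do.call(rbind, lapply(x$bands, function(b)
        data.frame(label = b$label, low = b$low, high = b$high,
                   stringsAsFactors = FALSE)))
    }
    instrument_spec(nm, x$n_items, x$item_min, x$item_max, bands = bands)
  })
  names(out) <- names(raw)
  out
}

#' @rdname read_instrument_registry
#' @param registry Named list of [instrument_spec()] objects.
#' @export
write_instrument_registry <- function(registry, path) {
  raw <- lapply(registry, function(s) {
    list(n_items = s$n_items, item_min = s$item_min, item_max = s$item_max,
         bands = lapply(seq_len(nrow(s$bands)), function(i)
           list(label = s$bands$label[i], low = s$bands$low[i],
                high = s$bands$high[i])))
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}
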