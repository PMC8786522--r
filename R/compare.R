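# Comparison tooling against the published reference temperature tables
# (shipped as plain CSV fixtures, transcribed exactly as printed including
# entries that violate the problem's own lateral mirror symmetry; those are
# flagged, never silently corrected).

#' Read a shipped reference table
#'
#' @param id `"table1"` .. `"table6"` (tables 1-3 are steady fields for the
#'   three fever cases; 4-6 the matching 2/4/6-minute transients), or a path
#'   to a CSV in the same layout.
#' @return `data.frame` with integer `i`, `j`, `k`, printed temperature
#'   columns kept as character (`T_C`, or `T_2min`/`T_4min`/`T_6min`), and a
#'   `note` column; attribute `kind` is `"steady"` or `"transient"`.
#' @export
read_reference_table <- function(id) {
  path <- if (file.exists(id)) id else
    system.file("extdata", paste0(id, ".csv"), package = "bioheat3d")
  if (!nzchar(path) || !file.exists(path)) {
    stop("read_reference_table: no fixture '", id, "'", call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character")
  for (col in c("i", "j", "k")) df[[col]] <- as.integer(df[[col]])
  attr(df, "kind") <- if ("T_C" %in% names(df)) "steady" else "transient"
  df
}

#' Serialize a reference table
#'
#' Writes the table back in the shipped fixture format; a freshly read
#' fixture round-trips byte-identically.
#'
#' @param df A table from [read_reference_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Audit a reference table for lateral mirror-symmetry violations
#'
#' The problem is symmetric under j -> -j and k -> -k, so printed values in
#' the same (i, |j|, |k|) group should agree; groups whose spread exceeds
#' the printed precision are flagged.
#'
#' @param ref A table from [read_reference_table()].
#' @param tol Spread tolerance (degrees C); default half a printed digit.
#' @return `data.frame` of flagged rows (with `group` and `spread` columns);
#'   zero rows when the table is symmetric.
#' @export
symmetry_audit <- function(ref, tol = 0.005) {
  vcols <- setdiff(names(ref), c("i", "j", "k", "note"))
  grp <- paste(ref$i, abs(ref$j), abs(ref$k), sep = ",")
  flagged <- lapply(vcols, function(col) {
    v <- as.numeric(ref[[col]])
    spread <- stats::ave(v, grp, FUN = function(z) max(z) - min(z))
    bad <- spread > tol
    if (!any(bad)) return(NULL)
    data.frame(ref[bad, c("i", "j", "k")], column = col,
               value = v[bad], group = grp[bad], spread = spread[bad])
  })
  out <- do.call(rbind, flagged)
  if (is.null(out)) {
    out <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                      column = character(0), value = numeric(0),
                      group = character(0), spread = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Compare computed fields against a reference table
#'
#' Per-node absolute deviations of the model from the printed values,
#' summary statistics, and the symmetry-suspect flags from
#' [symmetry_audit()]. Suspect rows can be excluded from the headline
#' maximum; they are never dropped from the per-node listing.
#'
#' @param fields A [temperature_field()] (steady tables) or a
#'   [run_transient()] result / list of fields (transient tables).
#' @param fixture Table id or path for [read_reference_table()], or an
#'   already-read table.
#' @param tol Agreement tolerance for the `n_within` count (degrees C).
#' @param exclude_suspects If `TRUE`, the headline `max` ignores rows
#'   flagged by the symmetry audit.
#' @return An object of class `comparison_report`.
#' @export
compare_reference <- function(fields, fixture, tol = 0.5, exclude_suspects = FALSE) {
  ref <- if (is.data.frame(fixture)) fixture else read_reference_table(fixture)
  kind <- attr(ref, "kind")
  if (is.null(kind)) kind <- if ("T_C" %in% names(ref)) "steady" else "transient"

  if (is.data.frame(fields)) {
    # long-format results (as written by write_results(layout = "long"))
    rows <- if (kind == "steady") {
      data.frame(ref[c("i", "j", "k")], time = NA_real_, ref = as.numeric(ref$T_C))
    } else {
      tcols <- grep("^T_[0-9]+min$", names(ref), value = TRUE)
      do.call(rbind, lapply(tcols, function(col) {
        data.frame(ref[c("i", "j", "k")],
                   time = as.numeric(sub("^T_([0-9]+)min$", "\\1", col)) * 60,
                   ref = as.numeric(ref[[col]]))
      }))
    }
    rkey <- paste(rows$i, rows$j, rows$k, ifelse(is.na(rows$time), 0, rows$time))
    fkey <- paste(fields$i, fields$j, fields$k,
                  if ("t_s" %in% names(fields)) ifelse(is.na(fields$t_s), 0, fields$t_s) else 0)
    hit <- match(rkey, fkey)
    if (anyNA(hit)) {
      stop("compare_reference: result file lacks ", sum(is.na(hit)),
           " node/time entries of the fixture", call. = FALSE)
    }
    rows$model <- as.numeric(fields$T_C[hit])
  } else if (kind == "steady") {
    fld <- if (inherits(fields, "temperature_field")) fields else fields[[1L]]
    rows <- data.frame(ref[c("i", "j", "k")], time = NA_real_,
                       ref = as.numeric(ref$T_C))
    rows$model <- mapply(function(i, j, k) field_at(fld, i, j, k),
                         rows$i, rows$j, rows$k)
  } else {
    fl <- if (inherits(fields, "transient_result")) fields$fields else fields
    times <- vapply(fl, `[[`, numeric(1), "time")
    tcols <- grep("^T_[0-9]+min$", names(ref), value = TRUE)
    rows <- do.call(rbind, lapply(tcols, function(col) {
      tt <- as.numeric(sub("^T_([0-9]+)min$", "\\1", col)) * 60
      at <- which(abs(times - tt) < 1e-6)
      if (length(at) != 1L) {
        stop("compare_reference: no snapshot at t = ", tt, " s for column ", col,
             call. = FALSE)
      }
      data.frame(ref[c("i", "j", "k")], time = tt, ref = as.numeric(ref[[col]]),
                 model = mapply(function(i, j, k) field_at(fl[[at]], i, j, k),
                                ref$i, ref$j, ref$k))
    }))
  }
  rows$dev <- abs(rows$model - rows$ref)
  rows$within <- rows$dev <= tol

  aud <- symmetry_audit(ref)
  akey <- paste(aud$i, aud$j, aud$k, aud$column)
  rkey <- if (kind == "steady") paste(rows$i, rows$j, rows$k, "T_C") else
    paste(rows$i, rows$j, rows$k, sprintf("T_%dmin", rows$time / 60))
  rows$suspect <- rkey %in% akey

  head_rows <- if (exclude_suspects) rows[!rows$suspect, ] else rows
  structure(list(
    fixture = if (is.character(fixture)) fixture else "table",
    kind = kind, tol = tol, nodes = rows, audit = aud,
    n = nrow(rows), n_within = sum(rows$within),
    max = max(head_rows$dev), mean = mean(rows$dev),
    excluded_suspects = exclude_suspects
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison vs %s (%s): %d entries, max |dT| = %.2f C%s, mean = %.2f C\n",
              x$fixture, x$kind, x$n, x$max,
              if (x$excluded_suspects) " (symmetry-suspects excluded)" else "",
              x$mean))
  cat(sprintf("  within %.2f C: %d / %d; symmetry-suspect fixture rows: %d\n",
              x$tol, x$n_within, x$n, nrow(x$audit)))
  miss <- x$nodes[!x$nodes$within, , drop = FALSE]
  if (nrow(miss)) {
    cat(sprintf("  %d entries miss the %.2f C band; largest at (%d,%d,%d%s): model %.2f vs printed %.2f\n",
                nrow(miss), x$tol,
                miss$i[which.max(miss$dev)], miss$j[which.max(miss$dev)],
                miss$k[which.max(miss$dev)],
                if (x$kind == "transient")
                  sprintf(", t=%gs", miss$time[which.max(miss$dev)]) else "",
                miss$model[which.max(miss$dev)], miss$ref[which.max(miss$dev)]))
  }
  invisible(x)
}

#' @export
as.data.frame.comparison_report <- function(x, ...) x$nodes
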