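#' Referencing schemes
#'
#' Virtual re-referencing of epoched potentials recorded against an ideal
#' remote ground (simulator output) or against the local tissue reference:
#'
#' * **LTR** (local tissue reference): `V(i) - V(REF)`, subtraction of the
#'   needle electrode in non-neural tissue;
#' * **DIFF** (differential): `V(i) - V(j)` where *j* is the next more caudal
#'   contact on the same lead;
#' * **REFk** (on-lead reference): `V(i) - V(k)` for a designated contact *k*
#'   (9 and 3 are the customary choices).
#'
#' @param kind One of `"LTR"`, `"DIFF"`, `"REF"`.
#' @param k Reference contact index, required when `kind = "REF"`.
#' @return An object of class `esr_ref_scheme`.
#' @examples
#' ref_scheme("REF", k = 9)
#' @export
ref_scheme <- function(kind = c("LTR", "DIFF", "REF"), k = NULL) {
  kind <- match.arg(kind)
  if (kind == "REF" && is.null(k)) {
    rlang::abort("REFk scheme requires a reference contact k", class = "esrkit_error_reference")
  }
  structure(list(kind = kind, k = if (!is.null(k)) as.integer(k) else NULL),
    class = "esr_ref_scheme"
  )
}

#' @export
print.esr_ref_scheme <- function(x, ...) {
  cat(sprintf("<esr_ref_scheme> %s\n", if (x$kind == "REF") paste0("REF", x$k) else x$kind))
  invisible(x)
}

#' Apply a referencing scheme to epoched data
#'
#' Pure subtraction algebra; no filtering is done here. Channels undefined
#' under the scheme are dropped: the stimulation contacts always, the
#' reference contact *k* under REFk (its re-referenced trace is identically
#' zero), and the most caudal contact of each lead (or a contact whose caudal
#' neighbour is a stimulation contact) under DIFF.
#'
#' Because all schemes are differences of the same potentials, a REFk
#' recording equals the difference of the two LTR recordings:
#' `REFk(i) = LTR(i) - LTR(k)`. Re-referencing LTR data therefore gives the
#' same result as referencing ground-based data directly.
#'
#' @param epochs An `esr_epochs` referenced to `"ground"` or `"LTR"`.
#' @param scheme An [ref_scheme()], or one of the strings `"LTR"`, `"DIFF"`,
#'   `"REF9"`, `"REF3"` (any `"REF<k>"`).
#' @return A new `esr_epochs` with `reference` set to the scheme name.
#' @export
apply_reference <- function(epochs, scheme) {
  stopifnot(inherits(epochs, "esr_epochs"))
  if (is.character(scheme)) {
    scheme <- if (grepl("^REF[0-9]+$", scheme)) {
      ref_scheme("REF", k = as.integer(sub("^REF", "", scheme)))
    } else {
      ref_scheme(scheme)
    }
  }
  ch <- epochs$channels
  if (!epochs$reference %in% c("ground", "LTR")) {
    rlang::abort("epochs must be referenced to ground or LTR before re-referencing",
      class = "esrkit_error_reference"
    )
  }

  keep_base <- !ch$is_stim & !ch$is_ref
  if (scheme$kind == "LTR") {
    if (epochs$reference != "ground") {
      rlang::abort("LTR requires ground-referenced input", class = "esrkit_error_reference")
    }
    ref_row <- which(ch$is_ref)
    if (length(ref_row) != 1) {
      rlang::abort("no reference electrode present", class = "esrkit_error_reference")
    }
    keep <- which(keep_base)
    ref_of <- rep(ref_row, length(keep))
    ref_label <- "LTR"
  } else if (scheme$kind == "REF") {
    k_row <- which(ch$channel == scheme$k & !ch$is_ref)
    if (length(k_row) != 1) {
      rlang::abort(sprintf("reference contact %d not found", scheme$k),
        class = "esrkit_error_reference"
      )
    }
    if (ch$is_stim[k_row]) {
      rlang::abort("reference contact must be a non-stimulation contact",
        class = "esrkit_error_reference"
      )
    }
    keep <- which(keep_base & ch$channel != scheme$k)
    ref_of <- rep(k_row, length(keep))
    ref_label <- paste0("REF", scheme$k)
  } else { # DIFF: next more caudal contact on the same lead (contact index + 1)
    neighbour <- match(
      paste(ch$lead, ch$channel + 1L),
      paste(ch$lead, ch$channel)
    )
    ok <- keep_base & !is.na(neighbour) & !ch$is_stim[pmax(neighbour, 1L)] &
      !ch$is_ref[pmax(neighbour, 1L)]
    keep <- which(ok)
    ref_of <- neighbour[keep]
    ref_label <- "DIFF"
  }

  d <- dim(epochs$data)
  out <- epochs$data[, keep, , drop = FALSE] - epochs$data[, ref_of, , drop = FALSE]

  new_esr_epochs(
    data = out,
    time_ms = epochs$time_ms,
    channels = ch[keep, ],
    trials = epochs$trials,
    sampling_rate_hz = epochs$sampling_rate_hz,
    stim_end_ms = epochs$stim_end_ms,
    reference = ref_label
  )
}
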