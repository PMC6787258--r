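# Lightweight container for one coordinate snapshot with bead roles.

#' Construct a labelled coordinate frame
#'
#' A `labeled_frame` holds one snapshot of bead/atom coordinates together with
#' a per-bead role (`"membrane_head"`, `"protein_backbone"` or `"other"`),
#' the periodic box lengths and a time stamp. All lengths are in nm.
#'
#' @param coords Numeric matrix (n x 3) of bead positions, nm.
#' @param role Character vector of length n with one of `"membrane_head"`,
#'   `"protein_backbone"`, `"other"` per bead.
#' @param box Numeric length-3 vector of periodic box lengths, nm.
#' @param time Time stamp, ps (default 0).
#' @param name Optional per-bead names (e.g. `"PO4"`, `"BB"`); used when
#'   writing coordinate files.
#' @return An object of class `labeled_frame`.
#' @export
#' @examples
#' fr <- labeled_frame(matrix(rnorm(30), 10, 3),
#'                     role = rep("membrane_head", 10),
#'                     box = c(10, 10, 10))
#' fr
labeled_frame <- function(coords, role, box, time = 0, name = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L) {
    rlang::abort("`coords` must be an n x 3 numeric matrix (nm).")
  }
  if (any(!is.finite(coords))) rlang::abort("All coordinates must be finite.")
  role <- as.character(role)
  if (length(role) != nrow(coords)) {
    rlang::abort("`role` must have one entry per coordinate row.")
  }
  bad <- setdiff(unique(role), c("membrane_head", "protein_backbone", "other"))
  if (length(bad)) {
    rlang::abort(paste0("Unknown roles: ", paste(bad, collapse = ", ")))
  }
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    rlang::abort("`box` must be three positive periodic box lengths (nm).")
  }
  if (is.null(name)) {
    name <- c(membrane_head = "PO4", protein_backbone = "BB",
              other = "X")[role]
  }
  dimnames(coords) <- NULL
  structure(
    list(coords = coords, role = role, box = box,
         time = as.numeric(time), name = as.character(name)),
    class = "labeled_frame"
  )
}

#' @export
print.labeled_frame <- function(x, ...) {
  cat(sprintf(
    "<labeled_frame> %d beads (%d membrane_head, %d protein_backbone), box %.3g x %.3g x %.3g nm, t = %g ps\n",
    nrow(x$coords), sum(x$role == "membrane_head"),
    sum(x$role == "protein_backbone"), x$box[1], x$box[2], x$box[3], x$time
  ))
  invisible(x)
}

#' @export
as_tibble.labeled_frame <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3],
    role = x$role, time = x$time
  )
}

frame_subset <- function(frame, idx) {
  labeled_frame(frame$coords[idx, , drop = FALSE], frame$role[idx],
                frame$box, frame$time, frame$name[idx])
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
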