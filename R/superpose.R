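#' Rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 translation vector (angstrom).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    abort("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", round(x$translation, 6), "\n")
  invisible(x)
}

ca_coords <- function(model, selection = NULL) {
  a <- as_tibble(model)
  a <- a[a$atom == "CA" & a$altloc %in% c("", "A"), ]
  if (!is.null(selection)) {
    sel <- as_tibble(selection)
    if (!"ins" %in% names(sel)) sel$ins <- ""
    a <- inner_join(a, sel[, c("chain", "resno", "ins")],
                    by = c("chain", "resno", "ins"))
  }
  a
}

#' Least-squares rigid superposition on C-alpha atoms
#'
#' Computes the Kabsch rotation and translation that superpose the mobile
#' model's C-alpha atoms onto the reference's, matching residues by
#' (chain, resno, ins). Residues missing a C-alpha in either model are
#' excluded with a warning. The mobile model is not modified; apply the
#' returned transform with [apply_transform()].
#'
#' @param mobile,reference [struct_model()]s sharing residue keys.
#' @param selection Optional residue selection restricting the fit.
#' @return List with `transform` (a [rigid_transform()]) and `rmsd`, the
#'   post-fit C-alpha RMSD in angstrom.
#' @export
superpose_calpha <- function(mobile, reference, selection = NULL) {
  ma <- ca_coords(mobile, selection)
  ra <- ca_coords(reference, selection)
  j <- inner_join(ma, ra, by = c("chain", "resno", "ins"),
                  suffix = c("_m", "_r"))
  n_dropped <- max(nrow(ma), nrow(ra)) - nrow(j)
  if (n_dropped > 0) {
    warn(sprintf("superpose_calpha: %d residue(s) lack a matched C-alpha and were excluded",
                 n_dropped))
  }
  if (nrow(j) < 3) abort("need at least 3 matched C-alpha pairs")
  P <- as.matrix(j[, c("x_m", "y_m", "z_m")])  # mobile
  Q <- as.matrix(j[, c("x_r", "y_r", "z_r")])  # reference
  fit <- kabsch(P, Q)
  rss <- sum((sweep(P, 2, fit$centroid_p) %*% t(fit$rotation) +
                matrix(fit$centroid_q, nrow(P), 3, byrow = TRUE) - Q)^2)
  list(transform = rigid_transform(fit$rotation,
                                   fit$centroid_q -
                                     as.numeric(fit$rotation %*% fit$centroid_p)),
       rmsd = sqrt(rss / nrow(P)))
}

# Kabsch algorithm: optimal rotation taking centred P onto centred Q
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2) abort("degenerate (collinear) C-alpha configuration")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, centroid_p = cp, centroid_q = cq)
}

#' Apply a rigid transform to a model
#'
#' @param model A [struct_model()].
#' @param transform A [rigid_transform()].
#' @return A new transformed model; the input is untouched.
#' @export
apply_transform <- function(model, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(transform$rotation)
  xyz <- sweep(xyz, 2, transform$translation, "+")
  out <- as_tibble(model)
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  rebuild_model(out, model)
}

#' Compose and invert rigid transforms
#'
#' @param a,b [rigid_transform()]s; `compose_transform(a, b)` applies `b`
#'   first, then `a`.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(a) {
  rigid_transform(t(a$rotation), -as.numeric(t(a$rotation) %*% a$translation))
}
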