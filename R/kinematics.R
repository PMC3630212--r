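#' Arm geometry for population-code simulations
#'
#' Constructs the deterministic geometry relating joint space, Cartesian hand
#' space and (in the one-dimensional variant) eye-centered space. The planar
#' two-link arm has the shoulder at the origin; \code{theta[1]} is the shoulder
#' angle measured from the x-axis and \code{theta[2]} the elbow flexion
#' relative to the upper-arm axis. All angles are in radians, all lengths in
#' centimeters.
#'
#' The default joint limits keep \code{sin(theta2) > 0} over the whole elbow
#' range, so the Jacobian determinant \code{L1*L2*sin(theta2)} never vanishes
#' and the forward map restricted to the limits is injective (checked
#' numerically on a grid at construction).
#'
#' @param link_lengths lengths of upper arm and forearm in cm.
#' @param joint_limits 2x2 matrix; rows are (lo, hi) for shoulder and elbow.
#' @param mode \code{"planar-2link"} or \code{"cosine-1d"}.
#' @param link_1d link length (cm) of the one-degree-of-freedom arm, whose
#'   hand position is \code{link_1d * cos(theta)}.
#' @param joint_limits_1d closed interval (rad) for the 1D joint.
#' @return an object of class \code{arm_model}.
#' @examples
#' arm <- arm_model()
#' forward_kinematics(c(pi/2, pi/2), arm)
#' @export
arm_model <- function(link_lengths = c(12, 20),
                      joint_limits = rbind(shoulder = c(pi / 4, 3 * pi / 4),
                                           elbow    = c(pi / 3, 5 * pi / 6)),
                      mode = c("planar-2link", "cosine-1d"),
                      link_1d = 32,
                      joint_limits_1d = c(0.4, pi - 0.4)) {
  mode <- match.arg(mode)
  if (any(!is.finite(link_lengths)) || any(link_lengths <= 0))
    stop("link lengths must be strictly positive and finite")
  joint_limits <- rbind(joint_limits)
  if (!is.matrix(joint_limits) || nrow(joint_limits) != 2L ||
      ncol(joint_limits) != 2L)
    stop("joint_limits must be a 2x2 matrix (rows: shoulder, elbow)")
  if (any(!is.finite(joint_limits)) || any(joint_limits[, 2] <= joint_limits[, 1]))
    stop("joint_limits must be finite, non-degenerate intervals")
  if (!is.finite(link_1d) || link_1d <= 0)
    stop("link_1d must be strictly positive")
  if (any(!is.finite(joint_limits_1d)) || joint_limits_1d[2] <= joint_limits_1d[1])
    stop("joint_limits_1d must be a finite, non-degenerate interval")
  arm <- structure(list(link_lengths = as.numeric(link_lengths),
                        joint_limits = unname(joint_limits),
                        mode = mode,
                        link_1d = as.numeric(link_1d),
                        joint_limits_1d = as.numeric(joint_limits_1d)),
                   class = "arm_model")
  if (mode == "planar-2link") .check_injective(arm)
  arm
}

# numerical injectivity check: forward/inverse must round-trip on a grid
.check_injective <- function(arm, n = 15L) {
  g1 <- seq(arm$joint_limits[1, 1], arm$joint_limits[1, 2], length.out = n)
  g2 <- seq(arm$joint_limits[2, 1], arm$joint_limits[2, 2], length.out = n)
  th <- as.matrix(expand.grid(g1, g2))
  x <- forward_kinematics(th, arm)
  back <- inverse_kinematics(x, arm)
  if (max(abs(back - th)) > 1e-6)
    stop("forward map is not injective on the configured joint limits")
  invisible(TRUE)
}

.check_limits <- function(theta, arm) {
  lim <- arm$joint_limits
  tol <- 1e-9
  for (j in 1:2) {
    bad <- theta[, j] < lim[j, 1] - tol | theta[, j] > lim[j, 2] + tol
    if (any(bad))
      stop(sprintf("joint %d (%s) outside limits [%g, %g]",
                   j, c("shoulder", "elbow")[j], lim[j, 1], lim[j, 2]))
  }
  invisible(TRUE)
}

.as_theta_matrix <- function(theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 2L)
  storage.mode(theta) <- "double"
  theta
}

#' Forward kinematics of the planar two-link arm
#'
#' Fingertip position \code{x = (L1 cos(t1) + L2 cos(t1 + t2),
#' L1 sin(t1) + L2 sin(t1 + t2))} with the shoulder at the origin.
#'
#' @param theta joint angles: a length-2 vector or an n x 2 matrix (rad).
#' @param arm an \code{\link{arm_model}}.
#' @return Cartesian position(s), same shape convention as \code{theta} (cm).
#' @export
forward_kinematics <- function(theta, arm) {
  vec <- is.null(dim(theta))
  theta <- .as_theta_matrix(theta)
  .check_limits(theta, arm)
  L <- arm$link_lengths
  a <- theta[, 1]
  b <- theta[, 1] + theta[, 2]
  out <- cbind(L[1] * cos(a) + L[2] * cos(b),
               L[1] * sin(a) + L[2] * sin(b))
  if (vec) drop(out) else out
}

#' Jacobian of the forward kinematics
#'
#' Analytic partial derivatives of \code{\link{forward_kinematics}} with
#' respect to the joint angles; \code{det(J) = L1*L2*sin(theta2)}.
#'
#' @inheritParams forward_kinematics
#' @param theta a length-2 joint-angle vector (rad).
#' @return a 2x2 matrix in cm/rad.
#' @export
jacobian <- function(theta, arm) {
  th <- .as_theta_matrix(theta)
  .check_limits(th, arm)
  L <- arm$link_lengths
  a <- th[1, 1]
  b <- th[1, 1] + th[1, 2]
  matrix(c(-L[1] * sin(a) - L[2] * sin(b), -L[2] * sin(b),
            L[1] * cos(a) + L[2] * cos(b),  L[2] * cos(b)),
         nrow = 2L, byrow = TRUE)
}

#' Inverse kinematics of the planar two-link arm
#'
#' Closed-form two-link solution. Of the two elbow branches, the one inside
#' the configured joint limits is returned; by the injectivity of the forward
#' map on the limits it is unique.
#'
#' @param x Cartesian position: a length-2 vector or an n x 2 matrix (cm).
#' @inheritParams forward_kinematics
#' @return joint angles with the same shape convention as \code{x} (rad).
#' @export
inverse_kinematics <- function(x, arm) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 2L)
  L <- arm$link_lengths
  r2 <- rowSums(x^2)
  c2 <- (r2 - L[1]^2 - L[2]^2) / (2 * L[1] * L[2])
  if (any(c2 > 1 + 1e-9) || any(c2 < -1 - 1e-9))
    stop("position outside the reachable workspace")
  c2 <- pmin(pmax(c2, -1), 1)
  t2a <- acos(c2)                       # elbow-up / elbow-down branches
  phi <- atan2(x[, 2], x[, 1])
  lim <- arm$joint_limits
  pick <- function(t2) {
    t1 <- phi - atan2(L[2] * sin(t2), L[1] + L[2] * cos(t2))
    # wrap t1 into the vicinity of the shoulder interval
    mid <- mean(lim[1, ])
    t1 <- t1 + 2 * pi * round((mid - t1) / (2 * pi))
    cbind(t1, t2)
  }
  tol <- 1e-7
  ok_branch <- function(th) {
    th[, 1] >= lim[1, 1] - tol & th[, 1] <= lim[1, 2] + tol &
      th[, 2] >= lim[2, 1] - tol & th[, 2] <= lim[2, 2] + tol
  }
  thA <- pick(t2a)
  thB <- pick(-t2a)
  okA <- ok_branch(thA)
  okB <- ok_branch(thB)
  if (any(!okA & !okB))
    stop("position reachable only with joints outside the configured limits")
  out <- thA
  out[!okA, ] <- thB[!okA, , drop = FALSE]
  colnames(out) <- NULL
  if (vec) drop(out) else out
}

#' One-dimensional cosine arm with gaze
#'
#' Maps a single joint angle to body-centered hand position
#' \code{H_b = L * cos(theta)} and, given a gaze angle \code{E} (expressed in
#' the same Cartesian units), to the retinal (eye-centered) position
#' \code{H_r = H_b - E}.
#'
#' @param theta joint angle(s), rad.
#' @param eye gaze position(s), cm.
#' @param arm an \code{\link{arm_model}} (uses \code{link_1d} and
#'   \code{joint_limits_1d}).
#' @return a list with components \code{body} and \code{retinal} (cm).
#' @export
forward_1d <- function(theta, eye, arm) {
  lim <- arm$joint_limits_1d
  tol <- 1e-9
  if (any(theta < lim[1] - tol | theta > lim[2] + tol))
    stop(sprintf("1D joint angle outside limits [%g, %g]", lim[1], lim[2]))
  body <- arm$link_1d * cos(theta)
  list(body = body, retinal = body - eye)
}

#' Inverse of the 1D cosine map
#'
#' @param body body-centered hand position(s), cm.
#' @inheritParams forward_1d
#' @return joint angle(s) in \code{joint_limits_1d} (rad).
#' @export
inverse_1d <- function(body, arm) {
  c_ <- body / arm$link_1d
  if (any(abs(c_) > 1 + 1e-9)) stop("body position outside the 1D workspace")
  th <- acos(pmin(pmax(c_, -1), 1))
  lim <- arm$joint_limits_1d
  tol <- 1e-7
  if (any(th < lim[1] - tol | th > lim[2] + tol))
    stop("body position maps outside the 1D joint limits")
  th
}
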