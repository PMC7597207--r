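# Diffusing molecular fields on a discretized 2D grid, with agent-local
# exchange. Concentrations are in mM; amounts exchanged with agents are in
# mM * um^3 ("amount units"), i.e. concentration times bin volume.

#' Create a molecular field
#'
#' @param grids Named list of `n_x x n_y` concentration matrices (mM), one per
#'   molecular species.
#' @param bin_size Bin edge length (um).
#' @param diffusion Named numeric: diffusion coefficient per species
#'   (um^2/s).
#' @param depth Out-of-plane depth used to convert bin area to volume (um);
#'   default 1.
#' @return A `cs_field`.
#' @export
make_field <- function(grids, bin_size, diffusion, depth = 1) {
  stopifnot(all(vapply(grids, function(g) all(g >= 0), TRUE)))
  structure(list(grids = grids, bin_size = bin_size,
                 diffusion = diffusion, depth = depth,
                 bounds = dim(grids[[1]]) * bin_size),
            class = "cs_field")
}

#' Build a uniform or exponential gradient field
#'
#' Exponential: `c(x, y) = c0 * exp((y - y0) / lambda)`, the profile a
#' chemotaxing cell can climb with a constant relative gradient.
#'
#' @param shape `"uniform"` or `"exponential"`.
#' @param nx,ny Grid dimensions.
#' @param bin_size Bin edge (um).
#' @param c0 Base concentration (mM, >= 0).
#' @param lambda Length scale of the exponential (um); `Inf` gives a uniform
#'   field.
#' @param y0 Reference height (um) where concentration equals `c0`.
#' @param species Species name.
#' @param diffusion Diffusion coefficient (um^2/s).
#' @return A `cs_field` with one species.
#' @export
make_gradient_field <- function(shape = c("uniform", "exponential"),
                                nx = 20, ny = 20, bin_size = 10,
                                c0 = 1, lambda = 100, y0 = 0,
                                species = "ligand", diffusion = 600) {
  shape <- match.arg(shape)
  if (c0 < 0) stop("base concentration must be nonnegative")
  ycent <- (seq_len(ny) - 0.5) * bin_size
  g <- matrix(c0, nx, ny)
  if (shape == "exponential" && is.finite(lambda)) {
    g <- outer(rep(1, nx), c0 * exp((ycent - y0) / lambda))
  }
  grids <- stats::setNames(list(g), species)
  make_field(grids, bin_size, stats::setNames(diffusion, species))
}

#' Diffuse a field for one explicit step
#'
#' Five-point discrete Laplacian with no-flux boundaries; total amount is
#' conserved to machine precision. The explicit scheme requires
#' `D * dt / bin_size^2 <= 0.25`; a violating step is a configuration error.
#'
#' @param field A `cs_field`.
#' @param dt Time-step (s).
#' @return The diffused field.
#' @export
diffuse_field <- function(field, dt) {
  h2 <- field$bin_size^2
  for (sp in names(field$grids)) {
    D <- field$diffusion[[sp]]
    if (is.null(D) || D == 0) next
    if (D * dt / h2 > 0.25 + 1e-12) {
      stop(sprintf("diffusion step unstable for '%s': D*dt/h^2 = %.3f > 0.25",
                   sp, D * dt / h2))
    }
    g <- field$grids[[sp]]
    nx <- nrow(g); ny <- ncol(g)
    up    <- g[c(1, seq_len(nx - 1)), , drop = FALSE]
    down  <- g[c(seq_len(nx - 1) + 1, nx), , drop = FALSE]
    left  <- g[, c(1, seq_len(ny - 1)), drop = FALSE]
    right <- g[, c(seq_len(ny - 1) + 1, ny), drop = FALSE]
    lap <- up + down + left + right - 4 * g
    field$grids[[sp]] <- g + D * dt / h2 * lap
  }
  field
}

# bin index (i, j) containing a location; error when outside the grid
field_bin <- function(field, location) {
  i <- floor(location[1] / field$bin_size) + 1
  j <- floor(location[2] / field$bin_size) + 1
  nx <- nrow(field$grids[[1]]); ny <- ncol(field$grids[[1]])
  if (i < 1 || i > nx || j < 1 || j > ny) {
    stop(sprintf("agent at (%.2f, %.2f) outside field bounds", location[1], location[2]))
  }
  c(i, j)
}

#' Bin volume of a field (um^3)
#' @param field A `cs_field`.
#' @export
bin_volume <- function(field) field$bin_size^2 * field$depth

#' Exchange molecules between agents and their local field bins
#'
#' Each agent maps to the bin containing its centroid. Its exchange (uptake
#' negative, secretion positive; in mM * um^3) is applied to that bin scaled
#' by bin volume. Bin concentrations are floored at zero; an uptake request
#' that exceeds local availability is truncated, with the granted amount
#' reported back.
#'
#' @param field A `cs_field`.
#' @param locations List of agent (x, y) locations.
#' @param exchanges List (one per agent) of named numeric vectors:
#'   species -> amount.
#' @return List with `field` (updated), `local` (list per agent: named mM
#'   concentrations of its bin after exchange), `granted` (list per agent of
#'   the exchange actually applied).
#' @export
agent_field_exchange <- function(field, locations, exchanges = NULL) {
  vol <- bin_volume(field)
  nag <- length(locations)
  granted <- vector("list", nag)
  for (a in seq_len(nag)) {
    ij <- field_bin(field, locations[[a]])
    ex <- if (is.null(exchanges)) NULL else exchanges[[a]]
    g <- numeric(0)
    for (sp in names(ex)) {
      if (is.null(field$grids[[sp]])) next
      conc <- field$grids[[sp]][ij[1], ij[2]]
      dconc <- ex[[sp]] / vol
      newc <- conc + dconc
      if (newc < 0) { dconc <- -conc; newc <- 0 }
      field$grids[[sp]][ij[1], ij[2]] <- newc
      g[sp] <- dconc * vol
    }
    granted[[a]] <- g
  }
  local <- lapply(seq_len(nag), function(a) {
    ij <- field_bin(field, locations[[a]])
    vapply(field$grids, function(g) g[ij[1], ij[2]], 0)
  })
  list(field = field, local = local, granted = granted)
}

#' Total amount of each species in a field (mM * um^3)
#' @param field A `cs_field`.
#' @export
field_totals <- function(field) {
  vol <- bin_volume(field)
  vapply(field$grids, function(g) sum(g) * vol, 0)
}
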