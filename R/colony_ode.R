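# Colony-site competition: allele-typed colonies seed empty sites and
# collapse at constant rates; competitive exclusion is decided by the
# seeding/collapse ratio.

#' Colony-site competition parameters
#'
#' A landscape of `M` colony sites. Colonies of allele type A (B) seed
#' empty sites at rate `kA * r` (`kB * r`) per colony, where
#' `r = M - A - B` is the number of available sites, and collapse at
#' per-colony rate `DA` (`DB`).
#'
#' @param M Total number of colony sites, > 0.
#' @param kA,kB Per-colony seeding rate constants, > 0.
#' @param DA,DB Per-colony collapse rates, > 0.
#' @return An object of class `colony_params`.
#' @export
colony_params <- function(M, kA, kB, DA, DB) {
  vals <- c(M = M, kA = kA, kB = kB, DA = DA, DB = DB)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals > 0))
  structure(as.list(vals), class = "colony_params")
}

#' Steady states of the colony-site competition
#'
#' The system has exactly three steady states: the trivial empty landscape
#' (`r = M`), and two competitive-exclusion states in which one allele
#' holds `M - r_i` sites with `r_i = D_i / k_i`. The stable state is the
#' exclusion state with the lower `r` (a state with more free sites is
#' invasible by the other type). Ties (`rA == rB`) are reported as neutral
#' rather than broken arbitrarily, and an allele with `r_i >= M` cannot
#' persist at all.
#'
#' @param p A [colony_params()] object.
#' @return A data.frame with one row per steady state (`trivial`,
#'   `A_excludes_B`, `B_excludes_A`) and columns `r`, `A`, `B`, `stable`,
#'   `feasible`; plus an attribute `winner` (`"A"`, `"B"`, `"tie"`, or
#'   `"none"`).
#' @examples
#' colony_steady_states(colony_params(M = 100, kA = 1, kB = 0.5, DA = 2, DB = 2))
#' @export
colony_steady_states <- function(p) {
  stopifnot(inherits(p, "colony_params"))
  rA <- p$DA / p$kA
  rB <- p$DB / p$kB
  feasA <- rA < p$M
  feasB <- rB < p$M
  winner <- if (!feasA && !feasB) "none"
  else if (feasA && !feasB) "A"
  else if (!feasA && feasB) "B"
  else if (rA < rB) "A" else if (rB < rA) "B" else "tie"
  out <- data.frame(
    state = c("trivial", "A_excludes_B", "B_excludes_A"),
    r = c(p$M, rA, rB),
    A = c(0, max(p$M - rA, 0), 0),
    B = c(0, 0, max(p$M - rB, 0)),
    feasible = c(TRUE, feasA, feasB),
    stable = c(!feasA && !feasB,
               winner == "A",
               winner == "B"),
    stringsAsFactors = FALSE
  )
  attr(out, "winner") <- winner
  out
}

#' Integrate the colony-site competition dynamics
#'
#' Explicit time stepping of
#' \deqn{dA/dt = (k_A r - D_A) A, \quad dB/dt = (k_B r - D_B) B, \quad
#'       r = M - A - B,}
#' (each colony seeds empty sites at per-colony rate \eqn{k r} and
#' collapses at per-colony rate \eqn{D}), with adaptive step halving
#' whenever a step would drive an abundance
#' negative. Site conservation `A + B + r = M` holds identically because
#' `r` is computed from it at every step.
#'
#' @param p A [colony_params()] object.
#' @param A0,B0 Initial colony counts (nonnegative, `A0 + B0 <= M`).
#' @param t_end Integration horizon.
#' @param dt Initial step size.
#' @return A data.frame with columns `t`, `A`, `B`, `r`.
#' @export
integrate_colony_ode <- function(p, A0, B0, t_end = 100, dt = 0.01) {
  stopifnot(inherits(p, "colony_params"), A0 >= 0, B0 >= 0,
            A0 + B0 <= p$M, t_end > 0, dt > 0)
  n_out <- 1000L
  t_grid <- seq(0, t_end, length.out = n_out + 1L)
  out <- matrix(NA_real_, nrow = n_out + 1L, ncol = 4L,
                dimnames = list(NULL, c("t", "A", "B", "r")))
  A <- A0; B <- B0; t <- 0; i_out <- 1L
  out[1L, ] <- c(0, A, B, p$M - A - B)
  for (i in 2:(n_out + 1L)) {
    t_target <- t_grid[i]
    while (t < t_target - 1e-12) {
      h <- min(dt, t_target - t)
      repeat {
        r <- p$M - A - B
        dA <- (p$kA * r - p$DA) * A
        dB <- (p$kB * r - p$DB) * B
        A_new <- A + h * dA
        B_new <- B + h * dB
        if (A_new >= 0 && B_new >= 0 && A_new + B_new <= p$M) break
        h <- h / 2
        if (h < 1e-12) stop("step size underflow in colony ODE integration")
      }
      A <- A_new; B <- B_new; t <- t + h
    }
    out[i, ] <- c(t_target, A, B, p$M - A - B)
  }
  as.data.frame(out)
}
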