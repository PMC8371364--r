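# Independent oracles used across the suite. These are written from the
# underlying mathematics, not from the package's implementation paths.

# Horn/Kearsley quaternion superposition: the minimal RMSD is obtained from
# the largest eigenvalue of the 4x4 key matrix of the centred coordinates.
quaternion_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(P, Q)  # sum_i p_i q_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / n
  sqrt(max(0, msd))
}

# direct transcription of the DFG-to-ATP-site distance definition
centroid_distance_oracle <- function(dfg_ca, ploop_ca, hinge_ca) {
  ctr <- function(m) colMeans(m)
  mid <- (ctr(ploop_ca) + ctr(hinge_ca)) / 2
  sqrt(sum((ctr(dfg_ca) - mid)^2))
}

# brute-force H-bond oracle: plain loops over every donor/hydrogen/acceptor
# triple, no spatial tricks, deviation-angle convention
hbond_bruteforce <- function(traj, frame, da_cutoff = 3.5,
                             angle_cutoff = 30) {
  top <- traj$topology
  xyz <- frame_coords(traj, frame)
  key <- paste(top$chain, top$res_seq, top$icode)
  nos <- which(top$element %in% c("N", "O", "S"))
  hs <- which(top$element == "H")
  found <- list()
  for (di in nos) {
    my_h <- c()
    for (hh in hs) {
      d_dh <- sqrt(sum((xyz[hh, ] - xyz[di, ])^2))
      if (d_dh <= 1.25) {
        # nearest-donor assignment
        dd <- sapply(nos, function(j) sqrt(sum((xyz[hh, ] - xyz[j, ])^2)))
        if (nos[which.min(dd)] == di) my_h <- c(my_h, hh)
      }
    }
    if (length(my_h) == 0) next
    for (ai in nos) {
      if (ai == di || key[ai] == key[di]) next
      if (top$name[di] == "N" && top$name[ai] == "O" &&
          top$chain[di] == top$chain[ai] &&
          abs(top$res_seq[di] - top$res_seq[ai]) == 1) next
      dda <- sqrt(sum((xyz[ai, ] - xyz[di, ])^2))
      if (dda >= da_cutoff) next
      for (hh in my_h) {
        v1 <- xyz[hh, ] - xyz[di, ]
        v2 <- xyz[ai, ] - xyz[di, ]
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang < angle_cutoff) {
          found[[length(found) + 1]] <- c(di, ai)
          break
        }
      }
    }
  }
  if (length(found) == 0) return(matrix(integer(), ncol = 2))
  unique(do.call(rbind, found))
}

# a bare-atoms topology at explicit coordinates, one atom per spec row
point_topology <- function(names, elements, res_seq, coords,
                           res_name = "ALA", is_het = FALSE) {
  top <- md_topology(seq_along(names), names, elements,
                     rep_len(res_name, length(names)), res_seq, "A",
                     is_het = is_het)
  md_trajectory(top, coords)
}
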