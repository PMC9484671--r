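# Independent oracles used across the suite.  These deliberately take
# the slow, direct route (closed forms, exhaustive enumeration, O(n^2)
# double loops) so they share no code path with the implementation.

# Area of two intersecting spheres of equal inflated radius R at
# centre distance d (union surface): each sphere loses a cap of height
# h = R - d/2.
two_sphere_area <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# O(n^2) Coulomb double loop, no vectorisation.
coulomb_bruteforce <- function(charged, target, dielectric = 1,
                               exclude_same_residue = TRUE) {
  k <- 332.0637
  e <- 0
  key <- paste(charged$chain, charged$resno, charged$insert)
  for (j in seq_len(nrow(charged))) {
    if (j == target) next
    if (exclude_same_residue && key[j] == key[target]) next
    r <- sqrt((charged$x[j] - charged$x[target])^2 +
                (charged$y[j] - charged$y[target])^2 +
                (charged$z[j] - charged$z[target])^2)
    if (r < 0.5) next
    e <- e + k * charged$charge[target] * charged$charge[j] /
      (dielectric * r)
  }
  e
}

# Exhaustive hydrogen-bond triple enumeration: for every hydrogen, the
# nearest covalent N/O donor within 1.2 A, then every N/O/S acceptor.
hbond_bruteforce <- function(model, d_a_cutoff = 3.0, angle_cutoff = 150) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  key <- paste(a$chain, a$resno, a$insert)
  res <- NULL
  for (h in seq_len(nrow(a))) {
    if (a$elem[h] != "H") next
    best <- NA; bestd <- 1.2
    for (d in seq_len(nrow(a))) {
      if (!a$elem[d] %in% c("N", "O")) next
      dd <- sqrt(sum((xyz[d, ] - xyz[h, ])^2))
      if (dd <= bestd) { best <- d; bestd <- dd }
    }
    if (is.na(best)) next
    for (acc in seq_len(nrow(a))) {
      if (!a$elem[acc] %in% c("N", "O", "S")) next
      if (acc == best || key[acc] == key[best]) next
      da <- sqrt(sum((xyz[acc, ] - xyz[best, ])^2))
      if (da > d_a_cutoff) next
      v1 <- xyz[best, ] - xyz[h, ]
      v2 <- xyz[acc, ] - xyz[h, ]
      ang <- acos(min(max(sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (ang >= angle_cutoff)
        res <- rbind(res, data.frame(donor = best, hydrogen = h,
                                     acceptor = acc))
    }
  }
  if (is.null(res))
    data.frame(donor = integer(), hydrogen = integer(),
               acceptor = integer())
  else res[order(res$hydrogen, res$acceptor), ]
}

# Independent nested-if restatement of the decision tree.
tree_oracle <- function(esa, pka, ss3, h_donor, flag) {
  if (esa < 50) return("non_reacting")
  if (pka > 10.3) return("slow_reacting")
  if (ss3 == "helix") return("slow_reacting")
  if (h_donor) return("slow_reacting")
  if (flag) "fast_reacting" else "slow_reacting"
}

rotate_structure <- function(model, angles = c(0.3, 1.1, -0.7),
                             shift = c(0, 0, 0)) {
  cx <- cos(angles); sx <- sin(angles)
  Rx <- rbind(c(1, 0, 0), c(0, cx[1], -sx[1]), c(0, sx[1], cx[1]))
  Ry <- rbind(c(cx[2], 0, sx[2]), c(0, 1, 0), c(-sx[2], 0, cx[2]))
  Rz <- rbind(c(cx[3], -sx[3], 0), c(sx[3], cx[3], 0), c(0, 0, 1))
  M <- Rz %*% Ry %*% Rx
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(M)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  out <- model
  out$atoms <- a
  out
}
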