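# Independent brute-force oracles and random-fixture generators.  These are
# deliberately written as plain scalar loops with their own formulas so they
# share no code path with the package implementation.

# exhaustive O(N^3) hydrogen-bond scan over all (donor, H, acceptor)
oracle_hbonds <- function(coords, top, max_da = 0.35, min_angle = 150,
                          scope = "ligand-all") {
  a <- top$atoms
  lig <- top$groups$ligand
  hits <- 0L
  ids <- character(0)
  bonds <- top$bonds
  for (d in seq_len(nrow(a))) {
    if (!isTRUE(a$is_donor_heavy[d])) next
    hs <- integer(0)
    for (k in seq_len(nrow(bonds))) {
      if (bonds[k, 1] == d && a$element[bonds[k, 2]] == "H")
        hs <- c(hs, bonds[k, 2])
      if (bonds[k, 2] == d && a$element[bonds[k, 1]] == "H")
        hs <- c(hs, bonds[k, 1])
    }
    for (h in hs) {
      for (acc in seq_len(nrow(a))) {
        if (!isTRUE(a$is_acceptor[acc]) || acc == d) next
        if (a$residue_index[acc] == a$residue_index[d] &&
            a$chain[acc] == a$chain[d]) next
        if (scope == "ligand-all" &&
            !xor(d %in% lig, acc %in% lig)) next
        da <- sqrt(sum((coords[d, ] - coords[acc, ])^2))
        if (da >= max_da) next
        v1 <- coords[d, ] - coords[h, ]
        v2 <- coords[acc, ] - coords[h, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2)) / sqrt(sum(v2^2))))) * 180 / pi
        if (ang > min_angle) {
          hits <- hits + 1L
          ids <- c(ids, paste(d, h, acc))
        }
      }
    }
  }
  list(count = hits, ids = sort(ids))
}

# exhaustive anion-cation pair scan
oracle_salt_bridges <- function(coords, top, max_dist = 0.7) {
  a <- top$atoms
  hits <- 0L
  ids <- character(0)
  for (p in seq_len(nrow(a))) {
    if (a$name[p] != "P") next
    for (ct in seq_len(nrow(a))) {
      ok <- (a$residue_name[ct] == "ARG" && a$name[ct] == "CZ") ||
        (a$residue_name[ct] == "LYS" && a$name[ct] == "NZ")
      if (!ok) next
      dd <- sqrt(sum((coords[p, ] - coords[ct, ])^2))
      if (dd <= max_dist) {
        hits <- hits + 1L
        ids <- c(ids, paste(p, ct))
      }
    }
  }
  list(count = hits, ids = sort(ids))
}

# brute-force ligand-environment double sum with its own switching formula
oracle_lig_env_energy <- function(coords, top, lig, cutoff = 1.2,
                                  switch_on = 1.0) {
  a <- top$atoms
  env <- setdiff(seq_len(nrow(a)), lig)
  vv <- 0
  ve <- 0
  for (i in lig) {
    for (j in env) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (r >= cutoff) next
      s2 <- switch_on^2
      c2 <- cutoff^2
      sw <- if (r <= switch_on) 1 else
        (c2 - r^2)^2 * (c2 + 2 * r^2 - 3 * s2) / (c2 - s2)^3
      eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
      rmin <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
      vv <- vv + eps * ((rmin / r)^12 - 2 * (rmin / r)^6) * sw
      ve <- ve + 33.2063711 * a$charge[i] * a$charge[j] / r * sw
    }
  }
  c(v_vdw = vv, v_el = ve)
}

# random donor/H/acceptor system in a compact box, with ligand group
random_contact_system <- function(seed, n_units = 8, n_extra = 20) {
  set.seed(seed)
  atoms <- list()
  coords <- list()
  bonds <- list()
  add <- function(name, resn, resi, pos) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, residue_name = resn, residue_index = resi, chain = "A",
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- pos
    length(atoms)
  }
  resi <- 0L
  for (k in seq_len(n_units)) {
    resi <- resi + 1L
    base <- runif(3, 0, 1.5)
    d <- add("OG", "SER", resi, base)
    h <- add("HG", "SER", resi, base + 0.1 * rnorm(3) / sqrt(3))
    add(paste0("O", k), "LIG", 999L, base + runif(3, -0.5, 0.5))
    bonds[[length(bonds) + 1L]] <- c(d, h)
  }
  # guarantee a resolvable anion/cation scope, then add random extras
  resi <- resi + 1L
  add("P", "LIG", 999L, runif(3, 0, 1.5))
  add("CZ", "ARG", resi, runif(3, 0, 1.5))
  for (k in seq_len(n_extra)) {
    resi <- resi + 1L
    who <- sample(3, 1)
    if (who == 1) add("P", "LIG", 999L, runif(3, 0, 1.5))
    else if (who == 2) add("CZ", "ARG", resi, runif(3, 0, 1.5))
    else add("NZ", "LYS", resi, runif(3, 0, 1.5))
  }
  top <- topology(do.call(rbind, atoms), bonds = do.call(rbind, bonds),
                  groups = list(ligand = which(vapply(atoms, function(x)
                    x$residue_name, character(1)) == "LIG")))
  top <- assign_donor_acceptor(top)
  list(topology = top, coords = do.call(rbind, coords))
}

# random charged LJ system for the energy oracle
random_energy_system <- function(seed, n = 30) {
  set.seed(seed)
  atoms <- data.frame(
    name = paste0("C", seq_len(n)), residue_name = "MOL",
    residue_index = rep(1:2, length.out = n), chain = "A",
    charge = round(runif(n, -1, 1), 3),
    lj_epsilon = round(runif(n, 0, 0.3), 4),
    lj_rmin_half = round(runif(n, 0.1, 0.25), 4),
    stringsAsFactors = FALSE)
  coords <- matrix(runif(3 * n, 0, 1.6), ncol = 3)
  # keep pairs off exact zero separation
  list(topology = topology(atoms), coords = coords,
       ligand = seq_len(max(2, n %/% 5)))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         nrow = 3, byrow = TRUE)
}
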