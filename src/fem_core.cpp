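// Corotational linear-tetrahedron FEM core.
//
// Unit system: mm / N / s / tonne (1 tonne * mm/s^2 = 1 N), i.e. the
// standard mm-N-s FEA convention: stiffness in N/mm (E supplied in MPa),
// lumped mass in tonnes, energies returned in mJ (N*mm).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat polar_rotation(const mat33& F) {
  mat U, V;
  vec s;
  svd(U, s, V, F);
  mat33 R = U * V.t();
  if (det(R) < 0) {
    U.col(2) *= -1.0;
    R = U * V.t();
  }
  return R;
}

// [[Rcpp::export]]
arma::mat polar_rotation_cpp(const arma::mat& F) {
  mat33 Fm = F;
  return polar_rotation(Fm);
}

// Per-element stiffness (12x12, N/mm) and rest shape inverses for linear
// tetrahedra. nodes: N x 3 (mm); tets: M x 4 1-based; E in MPa.
// [[Rcpp::export]]
Rcpp::List fem_precompute_cpp(const arma::mat& nodes, const arma::imat& tets,
                              double E_mpa, double nu) {
  const uword M = tets.n_rows;
  cube Ke(12, 12, M);
  cube DmInv(3, 3, M);
  vec vols(M);

  const double lambda = E_mpa * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  const double mu = E_mpa / (2.0 * (1.0 + nu));
  mat66 D(fill::zeros);
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) D(a, b) = lambda;
    D(a, a) = lambda + 2.0 * mu;
    D(a + 3, a + 3) = mu;
  }

  for (uword e = 0; e < M; ++e) {
    mat33 Dm;
    rowvec3 p0 = nodes.row(tets(e, 0) - 1);
    for (int c = 0; c < 3; ++c) {
      Dm.col(c) = (nodes.row(tets(e, c + 1) - 1) - p0).t();
    }
    double detDm = det(Dm);
    double V = detDm / 6.0;
    vols(e) = V;
    if (V <= 0) Rcpp::stop("degenerate or inverted element %d in stiffness assembly",
                           (int)(e + 1));
    mat33 Dmi = inv(Dm);
    DmInv.slice(e) = Dmi;

    // shape-function gradients: rows of Dm^{-1} are grad N_1..3; grad N_0 = -sum
    mat grads(4, 3);
    grads.row(1) = Dmi.row(0);
    grads.row(2) = Dmi.row(1);
    grads.row(3) = Dmi.row(2);
    grads.row(0) = -(grads.row(1) + grads.row(2) + grads.row(3));

    mat B(6, 12, fill::zeros);
    for (int a = 0; a < 4; ++a) {
      double bx = grads(a, 0), by = grads(a, 1), bz = grads(a, 2);
      int c = 3 * a;
      B(0, c) = bx;
      B(1, c + 1) = by;
      B(2, c + 2) = bz;
      B(3, c) = by; B(3, c + 1) = bx;
      B(4, c + 1) = bz; B(4, c + 2) = by;
      B(5, c) = bz; B(5, c + 2) = bx;
    }
    Ke.slice(e) = V * B.t() * D * B;
  }
  return Rcpp::List::create(Rcpp::Named("Ke") = Ke,
                            Rcpp::Named("DmInv") = DmInv,
                            Rcpp::Named("vols") = vols);
}

// Deformation gradients -> polar rotations. Elements whose nodes sit
// exactly at their rest positions get R = I, so the rest configuration is
// an exact zero of the force (no floating-point residue from Dm * Dm^-1).
// Returns first inverted element (1-based) in $inverted, or 0.
// [[Rcpp::export]]
Rcpp::List fem_rotations_cpp(const arma::mat& pos, const arma::mat& rest,
                             const arma::imat& tets, const arma::cube& DmInv) {
  const uword M = tets.n_rows;
  cube R(3, 3, M);
  int inverted = 0;
  for (uword e = 0; e < M; ++e) {
    bool at_rest = true;
    for (int a = 0; a < 4 && at_rest; ++a) {
      const uword n = tets(e, a) - 1;
      for (int c = 0; c < 3; ++c)
        if (pos(n, c) != rest(n, c)) { at_rest = false; break; }
    }
    if (at_rest) {
      R.slice(e).eye();
      continue;
    }
    mat33 Ds;
    rowvec3 p0 = pos.row(tets(e, 0) - 1);
    for (int c = 0; c < 3; ++c)
      Ds.col(c) = (pos.row(tets(e, c + 1) - 1) - p0).t();
    mat33 F = Ds * DmInv.slice(e);
    if (det(F) <= 0 && inverted == 0) inverted = (int)(e + 1);
    R.slice(e) = polar_rotation(F);
  }
  return Rcpp::List::create(Rcpp::Named("R") = R,
                            Rcpp::Named("inverted") = inverted);
}

// gather element dof vector (12) from an N x 3 array
static inline void gather(const mat& x, const imat& tets, uword e, vec& out) {
  for (int a = 0; a < 4; ++a) {
    const uword n = tets(e, a) - 1;
    out(3 * a) = x(n, 0);
    out(3 * a + 1) = x(n, 1);
    out(3 * a + 2) = x(n, 2);
  }
}

// apply block-diagonal rotation (R or R^T) to a 12-vector in place
static inline void rot_apply(const mat33& R, const vec& in, vec& out, bool transpose) {
  for (int a = 0; a < 4; ++a) {
    vec3 seg = {in(3 * a), in(3 * a + 1), in(3 * a + 2)};
    vec3 r = transpose ? vec3(R.t() * seg) : vec3(R * seg);
    out(3 * a) = r(0);
    out(3 * a + 1) = r(1);
    out(3 * a + 2) = r(2);
  }
}

// Corotational internal forces f = -sum_e S_e [ R_e K_e (R_e^T x_e - x0_e) ]
// and strain energy 0.5 sum d^T K d (mJ).
// [[Rcpp::export]]
Rcpp::List fem_forces_cpp(const arma::mat& pos, const arma::mat& rest,
                          const arma::imat& tets, const arma::cube& Ke,
                          const arma::cube& R) {
  const uword M = tets.n_rows;
  mat f(pos.n_rows, 3, fill::zeros);
  double energy = 0.0;
  vec xe(12), x0(12), d(12), t(12), fe(12);
  for (uword e = 0; e < M; ++e) {
    const mat33 Re = R.slice(e);
    gather(pos, tets, e, xe);
    gather(rest, tets, e, x0);
    rot_apply(Re, xe, t, true);   // R^T x
    d = t - x0;
    vec kd = Ke.slice(e) * d;
    energy += 0.5 * dot(d, kd);
    rot_apply(Re, kd, fe, false); // R K d
    for (int a = 0; a < 4; ++a) {
      const uword n = tets(e, a) - 1;
      f(n, 0) -= fe(3 * a);
      f(n, 1) -= fe(3 * a + 1);
      f(n, 2) -= fe(3 * a + 2);
    }
  }
  return Rcpp::List::create(Rcpp::Named("forces") = f,
                            Rcpp::Named("energy") = energy);
}

// y -> Ktilde y with Ktilde = sum_e S_e R_e K_e R_e^T S_e^T (matrix-free)
static void ktilde_mul(const mat& y, const imat& tets, const cube& Ke,
                       const cube& R, mat& out) {
  out.zeros();
  vec ye(12), t(12), kt(12), fe(12);
  const uword M = tets.n_rows;
  for (uword e = 0; e < M; ++e) {
    const mat33 Re = R.slice(e);
    gather(y, tets, e, ye);
    rot_apply(Re, ye, t, true);
    kt = Ke.slice(e) * t;
    rot_apply(Re, kt, fe, false);
    for (int a = 0; a < 4; ++a) {
      const uword n = tets(e, a) - 1;
      out(n, 0) += fe(3 * a);
      out(n, 1) += fe(3 * a + 1);
      out(n, 2) += fe(3 * a + 2);
    }
  }
}

static inline void project_fixed(mat& x, const uvec& fixed_idx) {
  for (uword i = 0; i < fixed_idx.n_elem; ++i) x.row(fixed_idx(i)).zeros();
}

// One backward Euler step with frozen corotational Jacobian and Rayleigh
// damping, solved by Jacobi-preconditioned constraint-projected CG.
//
// (M' + dt C + dt^2 (Ktilde + Kext)) dv
//     = dt (f_ext + f_int - C v) - dt^2 (Ktilde + Kext) v,
// C = alpha M' + beta Ktilde, M' lumped mass (tonnes). Kext is an optional
// per-node isotropic external spring stiffness (N/mm) used to fold stiff
// attachment springs (needle coupling) into the implicit solve; their force
// at the step start is part of f_ext. ext_c is the matching per-node
// external viscous coefficient (N s/mm, e.g. needle shaft friction), which
// enters the system matrix as dt * ext_c.
// [[Rcpp::export]]
Rcpp::List fem_step_cpp(const arma::mat& rest, const arma::mat& u0,
                        const arma::mat& v0, const arma::imat& tets,
                        const arma::cube& DmInv, const arma::cube& Ke,
                        const arma::vec& mass_t, const arma::uvec& fixed,
                        const arma::mat& f_ext, const arma::vec& ext_k,
                        const arma::vec& ext_c, double dt, double alpha,
                        double beta, double cg_tol, int cg_maxiter) {
  const uword N = rest.n_rows;
  mat pos = rest + u0;

  Rcpp::List rot = fem_rotations_cpp(pos, rest, tets, DmInv);
  int inverted = rot["inverted"];
  if (inverted > 0)
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("inverted") = inverted);
  cube R = rot["R"];

  Rcpp::List fi = fem_forces_cpp(pos, rest, tets, Ke, R);
  mat f_int = fi["forces"];
  double strain0 = fi["energy"];

  uvec fixed_idx = fixed - 1; // 1-based from R

  // C v
  mat Kv(N, 3);
  ktilde_mul(v0, tets, Ke, R, Kv);
  mat Cv = alpha * (v0.each_col() % mass_t) + beta * Kv;

  // consistent backward Euler linearisation: f_int(x1) ~ f_int(x0) - Ktilde dt v1,
  // hence the extra -dt^2 Ktilde v0 on the right-hand side (same for Kext)
  mat b = dt * (f_ext + f_int - Cv) - (dt * dt) * Kv -
    (dt * dt) * (v0.each_col() % ext_k);
  project_fixed(b, fixed_idx);

  const double mfac = 1.0 + dt * alpha;
  const double kfac = dt * beta + dt * dt;

  // Jacobi preconditioner diag(A)
  mat dK(N, 3, fill::zeros);
  {
    vec de(12);
    for (uword e = 0; e < tets.n_rows; ++e) {
      const mat33 Re = R.slice(e);
      const mat& K = Ke.slice(e);
      for (int a = 0; a < 4; ++a) {
        mat33 Kblk = K.submat(3 * a, 3 * a, 3 * a + 2, 3 * a + 2);
        mat33 blk = Re * Kblk * Re.t();
        const uword n = tets(e, a) - 1;
        dK(n, 0) += blk(0, 0);
        dK(n, 1) += blk(1, 1);
        dK(n, 2) += blk(2, 2);
      }
    }
  }
  mat dA = kfac * dK;
  dA.each_col() += mfac * mass_t + (dt * dt) * ext_k + dt * ext_c;

  // projected preconditioned CG
  mat dv(N, 3, fill::zeros);
  mat r = b; // A*0 = 0
  double bnorm = norm(vectorise(b), 2);
  double relres = 0.0;
  int iters = 0;
  bool converged = true;
  if (bnorm > 0) {
    mat z = r / dA;
    project_fixed(z, fixed_idx);
    mat p = z;
    double rz = accu(r % z);
    mat Ap(N, 3);
    converged = false;
    for (iters = 0; iters < cg_maxiter; ++iters) {
      ktilde_mul(p, tets, Ke, R, Ap);
      Ap *= kfac;
      Ap += mfac * (p.each_col() % mass_t) + (dt * dt) * (p.each_col() % ext_k) +
        dt * (p.each_col() % ext_c);
      project_fixed(Ap, fixed_idx);
      double pAp = accu(p % Ap);
      if (pAp <= 0) break;
      double a_step = rz / pAp;
      dv += a_step * p;
      r -= a_step * Ap;
      relres = norm(vectorise(r), 2) / bnorm;
      if (relres <= cg_tol) {
        converged = true;
        ++iters;
        break;
      }
      z = r / dA;
      project_fixed(z, fixed_idx);
      double rz_new = accu(r % z);
      p = z + (rz_new / rz) * p;
      rz = rz_new;
    }
  }

  mat v = v0 + dv;
  project_fixed(v, fixed_idx);
  mat u = u0 + dt * v;
  for (uword i = 0; i < fixed_idx.n_elem; ++i) u.row(fixed_idx(i)).zeros();

  // energies at end of step (strain energy with updated positions, frozen R)
  mat pos1 = rest + u;
  Rcpp::List rot1 = fem_rotations_cpp(pos1, rest, tets, DmInv);
  int inverted1 = rot1["inverted"];
  if (inverted1 > 0)
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("inverted") = inverted1);
  cube R1 = rot1["R"];
  Rcpp::List fi1 = fem_forces_cpp(pos1, rest, tets, Ke, R1);
  double strain1 = fi1["energy"];
  mat v2 = v % v;
  double kinetic = 0.5 * accu(v2.each_col() % mass_t);

  return Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("u") = u, Rcpp::Named("v") = v,
      Rcpp::Named("iterations") = iters, Rcpp::Named("relres") = relres,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("strain_energy_mJ") = strain1,
      Rcpp::Named("strain_energy_start_mJ") = strain0,
      Rcpp::Named("kinetic_energy_mJ") = kinetic,
      Rcpp::Named("inverted") = 0);
}
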