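#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Closed-form least-squares rigid fit (Kabsch with proper-rotation
// correction). Returns rotation R and centroids so that a point x of the
// moving set maps to (x - cx) * R^T + cy in the target frame.
static void kabsch_fit(const arma::mat& X, const arma::mat& Y,
                       arma::mat& R, arma::rowvec& cx, arma::rowvec& cy) {
  cx = arma::mean(X, 0);
  cy = arma::mean(Y, 0);

  // identical point sets need no fit: the optimal transform is the identity
  if (arma::accu(arma::square(X - Y)) < 1e-18) {
    R.eye(3, 3);
    cy = cx;
    return;
  }

  arma::mat Xc = X.each_row() - cx;
  arma::mat Yc = Y.each_row() - cy;

  // collinear point sets leave the rotation about the line undetermined
  arma::vec sx = arma::svd(Xc);
  arma::vec sy = arma::svd(Yc);
  if (sx(1) <= 1e-8 * std::max(1.0, sx(0)) ||
      sy(1) <= 1e-8 * std::max(1.0, sy(0)))
    stop("degenerate backbone fit: backbone atoms are (near-)collinear");

  arma::mat H = Xc.t() * Yc;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) stop("SVD failed in rigid fit");
  arma::mat D = arma::eye(3, 3);
  if (arma::det(V * U.t()) < 0.0) D(2, 2) = -1.0;
  R = V * D * U.t();
}

// [[Rcpp::export]]
arma::mat cpp_superpose(const arma::mat& frame, const arma::mat& ref,
                        const arma::uvec& bb) {
  arma::mat R;
  arma::rowvec cx, cy;
  kabsch_fit(frame.rows(bb), ref.rows(bb), R, cx, cy);
  arma::mat out = frame.each_row() - cx;
  out = out * R.t();
  out.each_row() += cy;
  return out;
}

// RMSD over ligand atoms of each frame after backbone superposition onto ref.
// frames: natoms x 3 x nframes cube; bb, lig: 0-based row indices.
// [[Rcpp::export]]
arma::vec cpp_ligand_rmsd_many(const arma::cube& frames, const arma::mat& ref,
                               const arma::uvec& bb, const arma::uvec& lig) {
  const arma::uword nf = frames.n_slices;
  arma::vec out(nf);
  arma::mat refbb = ref.rows(bb);
  arma::mat reflig = ref.rows(lig);
  arma::mat R;
  arma::rowvec cx, cy;
  for (arma::uword k = 0; k < nf; ++k) {
    const arma::mat& fr = frames.slice(k);
    kabsch_fit(fr.rows(bb), refbb, R, cx, cy);
    arma::mat L = fr.rows(lig);
    L.each_row() -= cx;
    L = L * R.t();
    L.each_row() += cy;
    arma::mat d = L - reflig;
    out(k) = std::sqrt(arma::accu(d % d) / static_cast<double>(lig.n_elem));
  }
  return out;
}
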