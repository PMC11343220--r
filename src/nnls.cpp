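#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares:
//   minimize ||A x - b||^2  subject to  x >= 0.
// Returns the solution, the residual norm and a convergence flag.
// The passive-set least-squares subproblems are solved by QR (arma::solve)
// for stability on the badly conditioned exponential dictionaries that
// arise in multi-exponential spectral analysis.
// [[Rcpp::export]]
Rcpp::List nnls_lh(const arma::mat& A, const arma::vec& b,
                   double tol = -1.0, int max_iter = -1) {
    const uword m = A.n_rows, n = A.n_cols;
    if (b.n_elem != m) Rcpp::stop("dim mismatch between A and b");
    if (max_iter < 0) max_iter = 5 * static_cast<int>(n);
    if (tol < 0) tol = 10.0 * datum::eps * norm(A, 1) * static_cast<double>(m);

    vec x(n, fill::zeros);
    std::vector<bool> passive(n, false);
    vec w = A.t() * b;              // gradient of -0.5||Ax-b||^2 at x=0
    bool converged = true;
    int iter = 0;

    for (;;) {
        // pick the active variable with the largest positive gradient
        double wmax = tol;
        sword t = -1;
        for (uword j = 0; j < n; ++j)
            if (!passive[j] && w(j) > wmax) { wmax = w(j); t = j; }
        if (t < 0) break;
        passive[t] = true;

        for (;;) {
            if (++iter > max_iter) { converged = false; goto done; }
            uvec P(n);
            uword np = 0;
            for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
            P.resize(np);

            vec z;
            bool ok = solve(z, A.cols(P), b, solve_opts::no_approx);
            if (!ok) { converged = false; goto done; }

            if (z.min() > 0.0) {
                x.zeros();
                for (uword k = 0; k < np; ++k) x(P(k)) = z(k);
                break;
            }
            // step back to the boundary of the feasible region
            double alpha = datum::inf;
            for (uword k = 0; k < np; ++k)
                if (z(k) <= 0.0) {
                    double a = x(P(k)) / (x(P(k)) - z(k));
                    if (a < alpha) alpha = a;
                }
            for (uword k = 0; k < np; ++k)
                x(P(k)) += alpha * (z(k) - x(P(k)));
            for (uword k = 0; k < np; ++k)
                if (x(P(k)) <= tol) { passive[P(k)] = false; x(P(k)) = 0.0; }
        }
        w = A.t() * (b - A * x);
    }
done:
    vec r = b - A * x;
    return Rcpp::List::create(Rcpp::Named("x") = x,
                              Rcpp::Named("rnorm") = norm(r, 2),
                              Rcpp::Named("converged") = converged,
                              Rcpp::Named("iterations") = iter);
}
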