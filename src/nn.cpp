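// Minimal 3D CNN engine: conv(3x3x3, same padding) -> batch norm ->
// activation -> max pool (2x2x2) blocks, global average pooling, dropout,
// dense head. Forward + backward with BCE / 2-class CE / confusion losses,
// weight gradients and input gradients (for SmoothGrad).
//
// Feature maps are arma::mat (channels x spatial), spatial linearized
// column-major over (x,y,z). Conv weights are (27*Cin x Cout); rows grouped
// per input channel, 27 kernel taps each, tap order dx fastest over
// (dx,dy,dz) in {-1,0,1}^3. All randomness (init, dropout masks, shuffling)
// lives on the R side, keeping runs a pure function of the R seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Dims { int x, y, z; int S() const { return x * y * z; } };

static void im2col(const arma::mat& in, const Dims& d, arma::mat& out) {
  const int Cin = in.n_rows, S = d.S();
  out.set_size(27 * Cin, S);
  out.zeros();
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        for (int z = 0; z < d.z; ++z) {
          int zz = z + dz; if (zz < 0 || zz >= d.z) continue;
          for (int y = 0; y < d.y; ++y) {
            int yy = y + dy; if (yy < 0 || yy >= d.y) continue;
            int x0 = std::max(0, -dx), x1 = std::min(d.x, d.x - dx);
            for (int x = x0; x < x1; ++x) {
              int xx = x + dx;
              int col = x + d.x * (y + d.y * z);
              int src = xx + d.x * (yy + d.y * zz);
              for (int c = 0; c < Cin; ++c)
                out(c * 27 + o, col) = in(c, src);
            }
          }
        }
      }
}

static void col2im_acc(const arma::mat& cols, const Dims& d, arma::mat& grad) {
  const int Cin = grad.n_rows;
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        for (int z = 0; z < d.z; ++z) {
          int zz = z + dz; if (zz < 0 || zz >= d.z) continue;
          for (int y = 0; y < d.y; ++y) {
            int yy = y + dy; if (yy < 0 || yy >= d.y) continue;
            int x0 = std::max(0, -dx), x1 = std::min(d.x, d.x - dx);
            for (int x = x0; x < x1; ++x) {
              int xx = x + dx;
              int col = x + d.x * (y + d.y * z);
              int src = xx + d.x * (yy + d.y * zz);
              for (int c = 0; c < Cin; ++c)
                grad(c, src) += cols(c * 27 + o, col);
            }
          }
        }
      }
}

// max pool 2x2x2 (dims must be even); records argmax linear index
static void maxpool(const arma::mat& in, const Dims& d, arma::mat& out,
                    arma::umat& idx, Dims& dout) {
  const int C = in.n_rows;
  dout = {d.x / 2, d.y / 2, d.z / 2};
  out.set_size(C, dout.S());
  idx.set_size(C, dout.S());
  for (int z = 0; z < dout.z; ++z)
    for (int y = 0; y < dout.y; ++y)
      for (int x = 0; x < dout.x; ++x) {
        int col = x + dout.x * (y + dout.y * z);
        for (int c = 0; c < C; ++c) {
          double best = -arma::datum::inf; unsigned bi = 0;
          for (int oz = 0; oz < 2; ++oz)
            for (int oy = 0; oy < 2; ++oy)
              for (int ox = 0; ox < 2; ++ox) {
                int src = (2 * x + ox) + d.x * ((2 * y + oy) + d.y * (2 * z + oz));
                double v = in(c, src);
                if (v > best) { best = v; bi = (unsigned)src; }
              }
          out(c, col) = best;
          idx(c, col) = bi;
        }
      }
}

// [[Rcpp::export]]
List cpp_cnn_run(List blocks, arma::mat headW, arma::vec headb,
                 NumericVector X, Nullable<NumericVector> yOpt,
                 Nullable<NumericVector> swOpt,
                 std::string activation, Nullable<NumericMatrix> dropMaskOpt,
                 bool training, std::string loss,
                 bool gradEncoder, bool gradHead, bool inputGrad,
                 double bnMomentum, double eps) {
  IntegerVector xd = X.attr("dim");
  Dims d0 = {xd[0], xd[1], xd[2]};
  const int nb = (xd.size() == 4) ? xd[3] : 1;
  const int B = blocks.size();
  const int K = headW.n_cols;
  const bool sigmoidAct = (activation == "sigmoid");
  const bool needBack = (loss != "none") &&
    (gradEncoder || gradHead || inputGrad);

  // unpack block parameters
  std::vector<arma::mat> W(B);
  std::vector<arma::vec> bb(B), gam(B), bet(B), rmean(B), rvar(B);
  for (int l = 0; l < B; ++l) {
    List bl = blocks[l];
    W[l] = as<arma::mat>(bl["W"]);
    bb[l] = as<arma::vec>(bl["b"]);
    gam[l] = as<arma::vec>(bl["gamma"]);
    bet[l] = as<arma::vec>(bl["beta"]);
    rmean[l] = as<arma::vec>(bl["run_mean"]);
    rvar[l] = as<arma::vec>(bl["run_var"]);
  }

  // per-layer caches
  std::vector<Dims> dims(B + 1);
  dims[0] = d0;
  std::vector<std::vector<arma::mat>> inmap(B + 1),  // input to block l
      xhat(B), act(B);
  std::vector<std::vector<arma::umat>> pidx(B);
  std::vector<arma::vec> bmean(B), bvar(B);
  for (int l = 0; l <= B; ++l) inmap[l].resize(nb);
  for (int l = 0; l < B; ++l) { xhat[l].resize(nb); act[l].resize(nb); pidx[l].resize(nb); }

  // load input batch
  const double* xp = X.begin();
  const int S0 = d0.S();
  for (int i = 0; i < nb; ++i)
    inmap[0][i] = arma::mat(1, S0, arma::fill::none),
    std::copy(xp + (size_t)i * S0, xp + (size_t)(i + 1) * S0, inmap[0][i].memptr());

  arma::mat cols; // scratch
  std::vector<arma::mat> conv(nb);
  for (int l = 0; l < B; ++l) {
    const int Cout = W[l].n_cols;
    // conv
    for (int i = 0; i < nb; ++i) {
      im2col(inmap[l][i], dims[l], cols);
      conv[i] = W[l].t() * cols;
      conv[i].each_col() += bb[l];
    }
    // batch norm statistics
    arma::vec mu(Cout), va(Cout);
    if (training) {
      mu.zeros(); va.zeros();
      const double N = (double)nb * dims[l].S();
      for (int i = 0; i < nb; ++i) mu += arma::sum(conv[i], 1);
      mu /= N;
      for (int i = 0; i < nb; ++i) {
        arma::mat c = conv[i];
        c.each_col() -= mu;
        va += arma::sum(arma::square(c), 1);
      }
      va /= N;
      rmean[l] = (1 - bnMomentum) * rmean[l] + bnMomentum * mu;
      rvar[l] = (1 - bnMomentum) * rvar[l] + bnMomentum * va;
    } else {
      mu = rmean[l]; va = rvar[l];
    }
    bmean[l] = mu; bvar[l] = va;
    arma::vec isd = 1.0 / arma::sqrt(va + eps);
    // normalize + activation + pool
    Dims dn;
    for (int i = 0; i < nb; ++i) {
      arma::mat xh = conv[i];
      xh.each_col() -= mu;
      xh.each_col() %= isd;
      xhat[l][i] = xh;
      arma::mat a = xh;
      a.each_col() %= gam[l];
      a.each_col() += bet[l];
      if (sigmoidAct) a = 1.0 / (1.0 + arma::exp(-a));
      else a = arma::clamp(a, 0.0, arma::datum::inf);
      act[l][i] = a;
      maxpool(a, dims[l], inmap[l + 1][i], pidx[l][i], dn);
    }
    dims[l + 1] = dn;
  }

  // global average pool -> dropout -> dense
  const int CF = (B > 0) ? (int)W[B - 1].n_cols : 1;
  const int SF = dims[B].S();
  arma::mat F(CF, nb); // pooled (pre-dropout)
  for (int i = 0; i < nb; ++i) F.col(i) = arma::mean(inmap[B][i], 1);
  arma::mat Fd = F;
  bool haveDrop = training && dropMaskOpt.isNotNull();
  arma::mat dmask;
  if (haveDrop) {
    dmask = as<arma::mat>(NumericMatrix(dropMaskOpt)); // CF x nb
    Fd %= dmask;
  }
  arma::mat Z = headW.t() * Fd; // K x nb
  Z.each_col() += headb;
  arma::mat P(K, nb);
  if (K == 1) P = 1.0 / (1.0 + arma::exp(-Z));
  else {
    for (int i = 0; i < nb; ++i) {
      arma::vec z = Z.col(i);
      z -= z.max();
      arma::vec e = arma::exp(z);
      P.col(i) = e / arma::accu(e);
    }
  }

  // loss + dZ
  arma::vec y, sw;
  if (yOpt.isNotNull()) y = as<arma::vec>(NumericVector(yOpt));
  if (swOpt.isNotNull()) sw = as<arma::vec>(NumericVector(swOpt));
  else sw = arma::vec(nb, arma::fill::ones);
  double swsum = arma::accu(sw);
  double lossVal = NA_REAL;
  arma::mat dZ(K, nb, arma::fill::zeros);
  const double tiny = 1e-12;
  if (loss == "bce") {
    double L = 0;
    for (int i = 0; i < nb; ++i) {
      double p = std::min(std::max(P(0, i), tiny), 1 - tiny);
      L += sw(i) * (-(y(i) * std::log(p) + (1 - y(i)) * std::log(1 - p)));
      dZ(0, i) = sw(i) * (P(0, i) - y(i)) / swsum;
    }
    lossVal = L / swsum;
  } else if (loss == "ce") {
    double L = 0;
    for (int i = 0; i < nb; ++i) {
      int cls = (int)y(i);
      L += sw(i) * (-std::log(std::max(P(cls, i), tiny)));
      for (int k = 0; k < K; ++k)
        dZ(k, i) = sw(i) * (P(k, i) - (k == cls ? 1.0 : 0.0)) / swsum;
    }
    lossVal = L / swsum;
  } else if (loss == "confusion") {
    double L = 0;
    const double u = 1.0 / K;
    for (int i = 0; i < nb; ++i) {
      for (int k = 0; k < K; ++k) {
        L += sw(i) * (-u * std::log(std::max(P(k, i), tiny)));
        dZ(k, i) = sw(i) * (P(k, i) - u) / swsum;
      }
    }
    lossVal = L / swsum;
  } else if (loss == "score") {
    lossVal = arma::accu(Z.row(0)) / nb;
    dZ.row(0).ones();
  }

  List out;
  out["prob"] = wrap(P.t()); // nb x K
  out["features"] = wrap(F.t()); // nb x CF pooled encoder features (pre-dropout)
  out["loss"] = lossVal;
  List rs(B);
  for (int l = 0; l < B; ++l)
    rs[l] = List::create(_["run_mean"] = wrap(rmean[l]), _["run_var"] = wrap(rvar[l]));
  out["run_stats"] = rs;

  if (!needBack) return out;

  // ---- backward ----
  arma::mat dHeadW = Fd * dZ.t(); // CF x K
  arma::vec dHeadb = arma::sum(dZ, 1);
  arma::mat dF = headW * dZ;      // CF x nb (gradient at dropout output)
  if (haveDrop) dF %= dmask;

  List gradOut;
  if (gradHead) {
    gradOut["headW"] = wrap(dHeadW);
    gradOut["headb"] = wrap(dHeadb);
  }

  if (gradEncoder || inputGrad) {
    // spread through global average pool
    std::vector<arma::mat> dmap(nb);
    for (int i = 0; i < nb; ++i) {
      dmap[i] = arma::mat(CF, SF);
      dmap[i].each_col() = dF.col(i) / (double)SF;
    }
    List bgrads(B);
    for (int l = B - 1; l >= 0; --l) {
      const int Cout = W[l].n_cols;
      const double N = (double)nb * dims[l].S();
      arma::vec isd = 1.0 / arma::sqrt(bvar[l] + eps);
      // pool backward + activation backward -> d(pre-activation)
      std::vector<arma::mat> dact(nb);
      arma::vec dgamma(Cout, arma::fill::zeros), dbeta(Cout, arma::fill::zeros);
      arma::vec sum_dxhat(Cout, arma::fill::zeros), sum_dxhat_xhat(Cout, arma::fill::zeros);
      for (int i = 0; i < nb; ++i) {
        arma::mat da(Cout, dims[l].S(), arma::fill::zeros);
        const arma::mat& po = inmap[l + 1][i];
        const arma::umat& pi = pidx[l][i];
        for (unsigned col = 0; col < po.n_cols; ++col)
          for (int c = 0; c < Cout; ++c)
            da(c, pi(c, col)) += dmap[i](c, col);
        if (sigmoidAct) da %= act[l][i] % (1.0 - act[l][i]);
        else {
          // relu: derivative 1 where activated output > 0
          da %= arma::conv_to<arma::mat>::from(act[l][i] > 0.0);
        }
        dact[i] = da; // gradient at BN output
        dgamma += arma::sum(da % xhat[l][i], 1);
        dbeta += arma::sum(da, 1);
      }
      // BN backward
      std::vector<arma::mat> dconv(nb);
      if (training) {
        for (int i = 0; i < nb; ++i) {
          arma::mat dxh = dact[i];
          dxh.each_col() %= gam[l];
          sum_dxhat += arma::sum(dxh, 1);
          sum_dxhat_xhat += arma::sum(dxh % xhat[l][i], 1);
        }
        for (int i = 0; i < nb; ++i) {
          arma::mat dxh = dact[i];
          dxh.each_col() %= gam[l];
          arma::mat t = dxh * N;
          t.each_col() -= sum_dxhat;
          t -= xhat[l][i].each_col() % sum_dxhat_xhat;
          t.each_col() %= (isd / N);
          dconv[i] = t;
        }
      } else {
        for (int i = 0; i < nb; ++i) {
          arma::mat dxh = dact[i];
          dxh.each_col() %= (gam[l] % isd);
          dconv[i] = dxh;
        }
      }
      // conv backward
      arma::mat dW(arma::size(W[l]), arma::fill::zeros);
      arma::vec db(Cout, arma::fill::zeros);
      bool needDx = (l > 0) ? gradEncoder || inputGrad : inputGrad;
      std::vector<arma::mat> dprev(nb);
      for (int i = 0; i < nb; ++i) {
        im2col(inmap[l][i], dims[l], cols);
        dW += cols * dconv[i].t();
        db += arma::sum(dconv[i], 1);
        if (needDx) {
          arma::mat dcols = W[l] * dconv[i];
          dprev[i] = arma::mat(inmap[l][i].n_rows, dims[l].S(), arma::fill::zeros);
          col2im_acc(dcols, dims[l], dprev[i]);
        }
      }
      bgrads[l] = List::create(_["W"] = wrap(dW), _["b"] = wrap(db),
                               _["gamma"] = wrap(dgamma), _["beta"] = wrap(dbeta));
      if (needDx) dmap = dprev; else break;
    }
    if (gradEncoder) gradOut["blocks"] = bgrads;
    if (inputGrad) {
      NumericVector gi(X.size());
      gi.attr("dim") = xd;
      double* gp = gi.begin();
      for (int i = 0; i < nb; ++i)
        std::copy(dmap[i].memptr(), dmap[i].memptr() + S0, gp + (size_t)i * S0);
      out["input_grad"] = gi;
    }
  }
  out["grads"] = gradOut;
  return out;
}
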