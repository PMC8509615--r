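"""SMILES ingestion helpers driven by the R package.

Modes
-----
canon  <in.tsv> <out.tsv>
    in:  compound_id <TAB> smiles
    out: compound_id <TAB> canonical isomeric SMILES ("" on parse failure)

embed  <in.tsv> <sdf_out> <status_out>
    in:  compound_id <TAB> smiles <TAB> seed
    out: multi-record SDF V2000 (molecule name = compound_id) of every
         successfully embedded conformer, plus a status TSV
         compound_id <TAB> ok|parse_error|embed_error <TAB> canonical_smiles

Embedding: largest covalent fragment, explicit hydrogens, ETKDGv3 with the
given 32-bit seed (retries with seed + 1000*attempt), MMFF94 minimization
with UFF fallback. Deterministic for a fixed (smiles, seed).
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def largest_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    return max(frags, key=lambda m: m.GetNumHeavyAtoms())


def canon(path_in, path_out):
    out = []
    with open(path_in) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            cid, smi = line.split("\t")[:2]
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                out.append(f"{cid}\t")
            else:
                mol = largest_fragment(mol)
                out.append(f"{cid}\t{Chem.MolToSmiles(mol)}")
    with open(path_out, "w") as fh:
        fh.write("\n".join(out) + "\n")


def embed_one(smi, seed):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return None, "parse_error", ""
    mol = largest_fragment(mol)
    csmi = Chem.MolToSmiles(mol)
    mol = Chem.AddHs(mol)
    ok = -1
    for attempt in range(3):
        params = AllChem.ETKDGv3()
        params.randomSeed = (int(seed) + 1000 * attempt) % (2**31 - 1)
        ok = AllChem.EmbedMolecule(mol, params)
        if ok == 0:
            break
    if ok != 0:
        return None, "embed_error", csmi
    try:
        if AllChem.MMFFHasAllMoleculeParams(mol):
            AllChem.MMFFOptimizeMolecule(mol, maxIters=500)
        else:
            AllChem.UFFOptimizeMolecule(mol, maxIters=500)
    except Exception:
        pass
    return mol, "ok", csmi


def embed(path_in, sdf_out, status_out):
    status = []
    writer = Chem.SDWriter(sdf_out)
    writer.SetForceV3000(False)
    with open(path_in) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            cid, smi, seed = line.split("\t")[:3]
            mol, st, csmi = embed_one(smi, seed)
            status.append(f"{cid}\t{st}\t{csmi}")
            if mol is not None:
                mol.SetProp("_Name", cid)
                writer.write(mol)
    writer.close()
    with open(status_out, "w") as fh:
        fh.write("\n".join(status) + "\n")


def main(argv):
    mode = argv[1]
    if mode == "canon":
        canon(argv[2], argv[3])
    elif mode == "embed":
        embed(argv[2], argv[3], argv[4])
    elif mode == "check":
        print(Chem.MolToSmiles(Chem.MolFromSmiles("CCO")))
    else:
        raise SystemExit(f"unknown mode {mode}")


if __name__ == "__main__":
    main(sys.argv)
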