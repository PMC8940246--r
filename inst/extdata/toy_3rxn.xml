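<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1" level="3" version="1" fbc:required="false" groups:required="false">
  <model id="toy3" fbc:strict="false">
    <listOfCompartments>
      <compartment id="e" constant="true"/>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfParameters>
      <parameter id="bnd_1" value="-2" constant="true"/>
      <parameter id="bnd_2" value="0" constant="true"/>
      <parameter id="bnd_3" value="5" constant="true"/>
      <parameter id="bnd_4" value="1000" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="M_A_e" name="A_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_B_c" name="B_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_R_up" name="R_up" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_3">
        <listOfProducts>
          <speciesReference species="M_A_e" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_R_conv" name="R_conv" reversible="true" fast="false" fbc:lowerFluxBound="bnd_1" fbc:upperFluxBound="bnd_4">
        <listOfReactants>
          <speciesReference species="M_A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_R_out" name="R_out" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_4">
        <listOfReactants>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj_1">
      <fbc:objective fbc:id="obj_1" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_R_out" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <groups:listOfGroups>
      <groups:group groups:id="g_1" groups:name="Core" groups:kind="partonomy">
        <groups:listOfMembers>
          <groups:member groups:idRef="R_R_conv"/>
        </groups:listOfMembers>
      </groups:group>
      <groups:group groups:id="g_2" groups:name="Exchange" groups:kind="partonomy">
        <groups:listOfMembers>
          <groups:member groups:idRef="R_R_up"/>
          <groups:member groups:idRef="R_R_out"/>
        </groups:listOfMembers>
      </groups:group>
    </groups:listOfGroups>
  </model>
</sbml>
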