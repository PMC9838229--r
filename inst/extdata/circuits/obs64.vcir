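# Sensory-motor substage 6 (observation 64, covered-box variant): invisible
# displacement. Extends the obs55 circuit with a mental-representation
# stage: watching the object placed in the box (open) and the box covered
# (close) is assimilated by two sensors on a separate memory stream and
# accommodated by an image thread whose ground instance is stored as a
# long-term trace {image(F(I)(X))}. When the box stops, a retrieval (LTR)
# fired by the watch thread relates it to the open effector and the box is
# opened; finding it empty triggers an LTB that permanently blocks further
# openings, and a retrieval-driven renew thread pops the FIFO memory of
# passed screens <look(Q(X+1))> to drive searches in the order the screens
# were passed. Screen-search failures re-fire the retrieval, walking the
# FIFO through successive invisible displacements.
circuit obs64
stream main
stream mem
node sensor main s_move move(obj(P,X))
node internal main expect expect(obj(P,X+1)) ttl=2
node sensor main s_see see(obj(Q,X+1))
node internal main cont cont(obj(P,X+1)) ttl=2
node internal main divert divert(obj(Q,X+1))
node sensor main s_halt halt(T)
node effector main grasp grasp(obj(P,X+1))
node effector main look look(obj(Q,X+1)) plasticity=push:looks
node effector main search search(T)
node sensor main s_view view(obj(P,X))
node sensor main s_stop stop(box(F,X))
node internal main watch watch(box(F,X)) ttl=8
node internal main spotd spot(box(F,X))
node sensor main s_failbox spot(box(F,empty,X))
node internal main fail fail(box(F,X))
node internal main recall recall(box(F,X))
node sensor main s_exc excite
node sensor mem s_open open(box(F,I,X)) ttl=2
node sensor mem s_close close(box(F,_,X))
node internal mem image image(box(F,I,X)) plasticity=lts
node effector main openeff open(box(F,X))
node internal main renew renew(box(F,I,X))
node sensor main s_failscr spot(obj(S,empty,X))
edge synapse s_move expect
edge conj expect cont w=0 plasticity=stp:expect:2 choice=attend
edge conj s_see cont as=see(obj(P,X+1))
edge conj expect divert w=0 plasticity=stp:expect:2 as=expect(obj(P0,X+1)) choice=attend
edge conj s_see divert
edge synapse divert look
edge conj cont grasp
edge conj s_halt grasp as=halt(obj(P,X+1))
edge synapse s_halt search w=0 plasticity=ltp:divert
edge synapse s_view grasp w=0 payload=grasp(obj(P,X)) plasticity=stp:search:2
edge synapse s_stop watch
edge synapse watch spotd w=1
edge modulation s_exc watch>spotd plasticity=ltd
edge synapse s_failbox fail
edge conj watch recall w=0 plasticity=ltp:s_exc
edge conj fail recall
edge synapse recall search pop=looks:look(Q) payload=search(Q)
edge conj s_open image
edge conj s_close image as=close(box(F,_,X))
edge choice watch openeff choice=boxact plasticity=ltr:image(box(F,I,X0))
edge modulation fail watch>openeff plasticity=ltb
edge choice watch renew choice=boxact payload=renew(box(F,I,X0)) plasticity=ltr:image(box(F,I,X0))
edge synapse fail renew payload=renew(box(F,I,X0)) plasticity=ltr:image(box(F,I,X0))
edge synapse s_failscr renew payload=renew(box(F,I,X0)) plasticity=ltr:image(box(F,I,X0))
edge synapse renew search pop=looks:look(Q) payload=search(Q)
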